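# Synthetic-data generator: determinism, architecture recovery, genotype
# marginals, family structure, phenotype construction.

test_that("generator is deterministic given the seed", {
  cfg <- small_cfg()
  expect_identical(simulate_effects(cfg), simulate_effects(cfg))
  p1 <- simulate_genotypes(cfg, "discovery", n = 30)
  p2 <- simulate_genotypes(cfg, "discovery", n = 30)
  expect_identical(p1$dosages, p2$dosages)
  c1 <- simulate_target_cohort(cfg)
  c2 <- simulate_target_cohort(cfg)
  expect_identical(c1$panel$dosages, c2$panel$dosages)
  expect_identical(simulate_phenotypes(c1), simulate_phenotypes(c2))
})

test_that("effect-pair correlation tracks the configured rg", {
  # independence
  cfg0 <- small_cfg(n_variants = 5000L, prop_causal = 1, rg = 0)
  e0 <- simulate_effects(cfg0)
  expect_lt(abs(cor(e0$beta_discovery, e0$beta_liability)), 0.05)
  # degenerate copula: proportional pairs
  cfg1 <- small_cfg(n_variants = 1000L, prop_causal = 1, rg = 1)
  e1 <- simulate_effects(cfg1)
  expect_equal(cor(e1$beta_discovery, e1$beta_liability), 1, tolerance = 1e-12)
  # rg = 0.5 recovered on average over seeds (2,000 causal variants each)
  cors <- vapply(1:20, function(s) {
    e <- simulate_effects(small_cfg(n_variants = 2000L, prop_causal = 1,
                                    rg = 0.5, seed = 100L + s))
    cor(e$beta_discovery[e$causal], e$beta_liability[e$causal])
  }, numeric(1))
  mc_se <- sd(cors) / sqrt(length(cors))
  expect_lt(abs(mean(cors) - 0.5), 3 * mc_se + 0.01)
  # non-causal variants have exactly zero effects
  cfg <- small_cfg(prop_causal = 0.2)
  e <- simulate_effects(cfg)
  expect_true(all(e$beta_discovery[!e$causal] == 0))
  expect_true(all(e$beta_liability[!e$causal] == 0))
  expect_error(sim_config(rg = 1.5), "rg")
})

test_that("genotype marginals match the configured allele frequencies", {
  cfg <- small_cfg(n_variants = 400L, maf_range = c(0.3, 0.3),
                   within_block_rho = 0)
  p <- simulate_genotypes(cfg, "discovery", n = 500)
  af <- colMeans(p$dosages) / 2
  # binomial CI on the grand mean over 400 x 1000 alleles
  expect_lt(abs(mean(af) - 0.3), 0.01)
  expect_true(all(af > 0.3 - 4 * sqrt(0.3 * 0.7 / 1000) - 0.02))
})

test_that("within-block LD is near zero when the copula correlation is zero", {
  cfg <- small_cfg(n_variants = 40L, block_size = 40L, within_block_rho = 0)
  p <- simulate_genotypes(cfg, "discovery", n = 400)
  r2 <- cor(p$dosages)^2
  mean_off <- mean(r2[upper.tri(r2)])
  expect_lt(mean_off, 0.01)  # E[r2] under independence is ~ 1/n
})

test_that("sibling pairs share about half their genotypic variance", {
  # per-variant correlation across sibling pairs (computed across pairs, not
  # across variants, so allele-frequency differences between variants do not
  # inflate the estimate)
  cors <- vapply(1:5, function(s) {
    cfg <- small_cfg(n_variants = 1000L, block_size = 50L, seed = 200L + s)
    sibs <- simulate_genotypes(cfg, "target-offspring", n = 100)
    mean(vapply(seq_len(1000), function(j)
      cor(sibs$sib1$dosages[, j], sibs$sib2$dosages[, j]), numeric(1)))
  }, numeric(1))
  expect_lt(abs(mean(cors) - 0.5), 0.02)
})

test_that("founder genotypes satisfy Hardy-Weinberg at generation", {
  cfg <- small_cfg(n_variants = 500L, seed = 7L)
  p <- simulate_genotypes(cfg, "target-founder", n = 300)
  pvals <- apply(p$dosages, 2, function(d)
    hwe_exact_test(sum(d == 0), sum(d == 1), sum(d == 2)))
  # exact-test rejection rate must not exceed the nominal level
  # (discreteness makes it conservative)
  expect_lt(mean(pvals < 0.05), 0.08)
  expect_gt(mean(pvals < 0.05), 0)
})

test_that("null discovery trait yields uniform p-values", {
  rates <- vapply(1:10, function(s) {
    cfg <- small_cfg(n_variants = 500L, within_block_rho = 0, h2_discovery = 0,
                     n_discovery = 200L, seed = 300L + s)
    ss <- simulate_discovery_sumstats(simulate_genotypes(cfg, "discovery"),
                                      simulate_effects(cfg), cfg)
    mean(ss$p_value < 0.05)
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.05), 0.015)
})

test_that("a very large true effect survives the strictest threshold", {
  cfg <- small_cfg(n_variants = 100L, within_block_rho = 0,
                   n_discovery = 5000L, h2_discovery = 0.5)
  eff <- simulate_effects(cfg)
  eff$beta_discovery[] <- 0
  eff$beta_discovery[50] <- 1  # one SD of trait per allele
  disc <- simulate_genotypes(cfg, "discovery")
  ss <- simulate_discovery_sumstats(disc, eff, cfg)
  expect_lt(ss$p_value[50], 1e-4)
})

test_that("monomorphic variants are flagged with weight 0 and p 1", {
  cfg <- small_cfg(n_variants = 20L, n_discovery = 80L)
  disc <- simulate_genotypes(cfg, "discovery")
  disc$dosages[, 3] <- 0
  ss <- simulate_discovery_sumstats(disc, simulate_effects(cfg), cfg)
  expect_true(ss$monomorphic[3])
  expect_identical(ss$weight[3], 0)
  expect_identical(ss$p_value[3], 1)
})

test_that("liability threshold is the prevalence quantile", {
  expect_equal(liability_threshold(0.5), 0)
  expect_equal(liability_threshold(0.01), qnorm(0.99))
  expect_error(liability_threshold(0), "prevalence")
})

test_that("ascertained cohort respects group sizes and case liabilities", {
  cfg <- small_cfg(seed = 9L)
  coh <- simulate_target_cohort(cfg)
  expect_equal(as.vector(table(coh$group)[c("SCZ", "FR", "HC")]),
               c(cfg$n_cases, cfg$n_relatives, cfg$n_controls))
  expect_true(all(coh$liability[coh$group == "SCZ"] > coh$threshold))
  expect_true(all(coh$liability[coh$group != "SCZ"] <= coh$threshold))
})

test_that("an unreachable prevalence errors informatively", {
  cfg <- small_cfg(prevalence = 1e-4, n_cases = 50L, n_relatives = 0L,
                   n_controls = 5L, n_variants = 50L)
  expect_error(simulate_target_cohort(cfg), "unreachable|batches")
})

test_that("smoking trait is independent of case status when rg is zero", {
  cfg <- small_cfg(n_variants = 500L, rg = 0, n_cases = 60L,
                   n_relatives = 0L, n_controls = 60L, seed = 11L)
  coh <- simulate_target_cohort(cfg)
  ph <- simulate_phenotypes(coh)
  r <- cor(as.numeric(coh$group == "SCZ"),
           as.numeric(ph$ever_smoker))
  expect_lt(abs(r), 3 / sqrt(nrow(ph)))  # sampling bound
})

test_that("phenotype table respects smoker-field missingness", {
  coh <- simulate_target_cohort(small_cfg())
  ph <- simulate_phenotypes(coh)
  expect_s3_class(ph, "phenotype_table")
  never <- !ph$ever_smoker
  expect_true(all(is.na(ph$age_initiation[never])))
  expect_true(all(is.na(ph$cpd[never])))
  expect_true(all(!is.na(ph$age_initiation[!never])))
  expect_true(all(is.na(ph$onset_age[ph$group != "SCZ"])))
  # validates against its own reader contract
  expect_silent(validate_phenotypes(ph))
})

test_that("fixture sets are byte-reproducible and self-consistent", {
  cfg <- small_cfg(n_variants = 120L, n_discovery = 60L, n_cases = 8L,
                   n_relatives = 3L, n_controls = 10L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- generate_fixture_set(cfg, d1)
  m2 <- generate_fixture_set(cfg, d2)
  expect_identical(m1$md5, m2$md5)  # same seed, same bytes
  # 4 configured traits -> 4 summary-statistic files in the manifest
  expect_length(grep("^sumstats_", m1$file), 4L)
  # read-back dimensions match the config
  ss <- read_summary_stats(file.path(d1, "sumstats_age_initiation.tsv"))
  expect_equal(nrow(ss), cfg$n_variants)
  pan <- read_dosages(file.path(d1, "target_dosages.tsv"))
  expect_equal(dim(pan$dosages),
               c(cfg$n_cases + cfg$n_relatives + cfg$n_controls, cfg$n_variants))
  vcf <- read_dosages(file.path(d1, "target_dosages.vcf"), "vcf-dosage")
  expect_equal(unname(vcf$dosages), unname(pan$dosages))
  ph <- read_phenotypes(file.path(d1, "phenotypes.tsv"))
  expect_equal(nrow(ph), nrow(pan$dosages))
})
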