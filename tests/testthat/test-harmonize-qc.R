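# Strand ambiguity, Hardy-Weinberg exact test, variant QC, allele
# harmonization.

test_that("strand ambiguity is exactly the complement pairs", {
  expect_true(is_strand_ambiguous("A", "T"))
  expect_false(is_strand_ambiguous("A", "G"))
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(a1 = bases, a2 = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a1 != pairs$a2, ]
  amb <- is_strand_ambiguous(pairs$a1, pairs$a2)
  expect_equal(sum(amb), 4L)  # A/T, T/A, C/G, G/C among the 12 ordered pairs
  expect_error(is_strand_ambiguous("A", "N"), "non-ACGT")
})

test_that("HWE exact test handles the edge configurations", {
  expect_equal(hwe_exact_test(100, 0, 0), 1)  # monomorphic
  # perfectly HWE-proportioned table: observed het count is the mode
  expect_equal(hwe_exact_test(25, 50, 25), oracle_hwe(25, 50, 25))
  # extreme heterozygote excess
  p <- hwe_exact_test(0, 100, 0)
  expect_lt(p, 1e-6)
  expect_equal(p, oracle_hwe(0, 100, 0), tolerance = 1e-9)
  expect_error(hwe_exact_test(0, 0, 0), "at least 1")
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
})

test_that("HWE exact test agrees with the recurrence oracle up to n = 200", {
  set.seed(1)
  for (i in 1:60) {
    n <- sample(1:200, 1)
    counts <- as.vector(stats::rmultinom(1, n, prob = runif(3)))
    expect_equal(hwe_exact_test(counts[1], counts[2], counts[3]),
                 oracle_hwe(counts[1], counts[2], counts[3]),
                 tolerance = 1e-9,
                 info = paste(counts, collapse = "/"))
  }
})

test_that("variant QC applies each rule with the documented reasons", {
  set.seed(2)
  n <- 120
  hwe_ok <- function() rbinom(n, 2, 0.3)
  dos <- cbind(hwe_ok(), hwe_ok(),            # duplicated id pair
               hwe_ok(),                      # ambiguous alleles
               hwe_ok(),                      # chromosome Y
               hwe_ok(),                      # low info
               c(1, rep(0, n - 1)),           # low MAF
               rep(1, n),                     # all heterozygous: HWE fails
               hwe_ok(), hwe_ok(), hwe_ok())  # clean survivors
  p <- make_panel(dos,
                  ids = c("d", "d", paste0("v", 3:10)),
                  chrom = c("1", "1", "1", "Y", "2", "2", "2", "3", "3", "3"),
                  ref = c("A", "A", "A", "A", "C", "C", "C", "G", "G", "G"),
                  alt = c("G", "G", "T", "G", "T", "T", "T", "A", "A", "A"),
                  info = c(1, 1, 1, 1, 0.85, 1, 1, 0.99, 0.95, 1))
  qc <- variant_qc(p, qc_thresholds())
  expect_equal(length(qc$keep), 3L)
  expect_setequal(qc$keep, c("v8", "v9", "v10"))
  rules <- setNames(qc$exclusions$rule, qc$exclusions$variant_id)
  expect_equal(unname(rules[c("v4", "v5", "v6", "v7")]),
               c("chromosome", "info", "maf", "hwe"))
  expect_equal(sum(rules == "duplicate"), 2L)
  expect_equal(sum(rules == "ambiguous"), 1L)
})

test_that("HWE screening can be restricted to a sample subset", {
  set.seed(5)
  n <- 200
  # equilibrium among the first 100 founders, all-het among the rest
  dos <- cbind(c(rbinom(100, 2, 0.4), rep(1, 100)),
               rbinom(n, 2, 0.4))
  p <- make_panel(dos)
  all_samp <- variant_qc(p, qc_thresholds())
  expect_true("s001" %in% all_samp$exclusions$variant_id)
  founders <- variant_qc(p, qc_thresholds(), hwe_samples = p$samples[1:100])
  expect_false("s001" %in% founders$exclusions$variant_id)
  expect_error(variant_qc(p, qc_thresholds(), hwe_samples = "ghost"),
               "not in panel")
})

test_that("QC survivor set is invariant to variant order", {
  set.seed(3)
  n <- 80
  dos <- vapply(runif(12, 0.1, 0.4), function(q) rbinom(n, 2, q),
                numeric(n))
  dos[, 4] <- 0  # monomorphic -> maf rule
  p <- make_panel(dos, ref = rep(c("A", "A", "C"), 4),
                  alt = rep(c("G", "T", "G"), 4))
  perm <- sample(12)
  p_perm <- make_panel(dos[, perm],
                       ids = p$variants$variant_id[perm],
                       ref = p$variants$ref[perm], alt = p$variants$alt[perm])
  k1 <- variant_qc(p, qc_thresholds())$keep
  k2 <- variant_qc(p_perm, qc_thresholds())$keep
  expect_setequal(k1, k2)
})

test_that("allele harmonization matches the 12-configuration truth table", {
  bases <- c("A", "C", "G", "T")
  targets <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  targets <- targets[targets$ref != targets$alt, ]
  # discovery record: effect A, other G, weight +0.5
  expected <- function(ref, alt) {
    if (alt == "A" && ref == "G") return(c("direct", 0.5))
    if (alt == "G" && ref == "A") return(c("flipped", -0.5))
    if (alt == "T" && ref == "C") return(c("complement-direct", 0.5))
    if (alt == "C" && ref == "T") return(c("complement-flipped", -0.5))
    c("excluded(mismatch)", NA)
  }
  for (i in seq_len(nrow(targets))) {
    ss <- data.frame(variant_id = "v", chromosome = "1", position = 1L,
                     effect_allele = "A", other_allele = "G",
                     weight = 0.5, p_value = 0.1)
    tv <- data.frame(variant_id = "v", ref = targets$ref[i],
                     alt = targets$alt[i])
    h <- harmonize_alleles(ss, tv)
    exp <- expected(targets$ref[i], targets$alt[i])
    expect_equal(h$match_type, exp[1],
                 info = paste("target", targets$ref[i], targets$alt[i]))
    if (is.na(exp[2])) expect_true(is.na(h$aligned_weight))
    else expect_equal(h$aligned_weight, as.numeric(exp[2]))
  }
})

test_that("ambiguous discovery pairs are never complement-matched", {
  ss <- data.frame(variant_id = "v", chromosome = "1", position = 1L,
                   effect_allele = "A", other_allele = "T",
                   weight = 0.3, p_value = 0.1)
  # direct reading works
  h1 <- harmonize_alleles(ss, data.frame(variant_id = "v", ref = "T", alt = "A"))
  expect_equal(h1$match_type, "direct")
  # a C/G target cannot be reconciled with an A/T discovery pair
  h2 <- harmonize_alleles(ss, data.frame(variant_id = "v", ref = "C", alt = "G"))
  expect_equal(h2$match_type, "excluded(mismatch)")
})

test_that("harmonization is flip-invariant and idempotent", {
  set.seed(4)
  tv <- data.frame(variant_id = paste0("v", 1:6),
                   ref = c("A", "C", "G", "T", "A", "C"),
                   alt = c("G", "T", "A", "C", "C", "A"))
  ss <- data.frame(variant_id = tv$variant_id, chromosome = "1",
                   position = 1:6,
                   effect_allele = c("G", "T", "G", "C", "A", "C"),
                   other_allele = c("A", "C", "A", "T", "C", "A"),
                   weight = rnorm(6), p_value = runif(6))
  h <- harmonize_alleles(ss, tv)
  # swapping discovery alleles and negating the weight leaves the aligned
  # weight unchanged
  ss_flip <- ss
  ss_flip$effect_allele <- ss$other_allele
  ss_flip$other_allele <- ss$effect_allele
  ss_flip$weight <- -ss$weight
  h_flip <- harmonize_alleles(ss_flip, tv)
  expect_equal(h_flip$aligned_weight, h$aligned_weight)
  # re-harmonizing the already-aligned orientation reproduces the weights
  ss2 <- ss
  ss2$effect_allele <- tv$alt
  ss2$other_allele <- tv$ref
  ss2$weight <- h$aligned_weight
  h2 <- harmonize_alleles(ss2, tv)
  expect_equal(h2$aligned_weight, h$aligned_weight)
  expect_true(all(h2$match_type == "direct"))
})
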