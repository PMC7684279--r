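# Simulation-based calibration checks: type-I error of the PRS association
# at a pre-fixed cutoff (and the selection inflation of the best-cutoff
# scan), power under a moderate genetic correlation, recovery of the
# case > relative > control ordering, and monotonicity of variance explained
# in the discovery sample size. These run the same generator and scoring
# machinery as the pipeline itself.

#' Simulate a quantitative target trait for a founder panel
#'
#' Builds the liability-side genetic value of each individual, standardizes
#' it in-sample, and adds Gaussian environment so the trait heritability is
#' `h2_liability` and its genetic correlation with the discovery trait is the
#' configured `rg`.
#'
#' @param panel a founder [dosage_panel()].
#' @param effects a `true_effects` frame.
#' @param config the [sim_config()].
#' @param stream integer sub-stream for the environmental noise.
#' @return numeric trait vector, one value per sample.
#' @export
simulate_target_trait <- function(panel, effects, config, stream = 0L) {
  set.seed(sim_seed(config, 809 + 7 * stream))
  g <- as.vector(panel$dosages %*% effects$beta_liability)
  gs <- if (sd(g) > 0) as.vector(scale(g)) else rep(0, length(g))
  h2 <- config$h2_liability
  sqrt(h2) * gs + rnorm(length(g), 0, sqrt(1 - h2))
}

# score a target panel against simulated summary statistics and scan the
# threshold grid against a supplied outcome
score_and_scan <- function(target, sumstats, y, model = "linear",
                           grid = default_grid()) {
  h <- harmonize_alleles(sumstats, target$variants)
  prof <- suppressWarnings(prs_profile(target, h, grid))
  scan_thresholds(prof, y, model = model)
}

#' Type-I error of the PRS association under a null genetic correlation
#'
#' Repeatedly simulates a discovery GWAS and an independent target cohort
#' with `rg = 0` (the target trait's genetics are independent of the
#' discovery trait's), scores the target, and tests the PRS-trait
#' association. Reports the rejection rate at the pre-fixed cutoff
#' `P_T <= 1` -- which should sit at the nominal 5% -- and, for contrast, the
#' rejection rate of the uncorrected best-cutoff scan, which is inflated by
#' selection. Replicate cohorts are deliberately small (2,000 independent
#' variants, 500 discovery / 200 target samples) so the score's chance
#' overlap with the trait's genetic value stays negligible relative to
#' sampling noise.
#'
#' @param n_reps number of replicates (default 200).
#' @param seed base seed.
#' @param alpha nominal level (default 0.05).
#' @return list with `fixed_rate`, `best_rate`, `n_reps`, `rejections`.
#' @export
prs_type1_calibration <- function(n_reps = 200L, seed = 1L, alpha = 0.05) {
  fixed_rej <- best_rej <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    cfg <- sim_config(n_variants = 2000L, block_size = 50L,
                      within_block_rho = 0, prop_causal = 0.1,
                      h2_discovery = 0.5, h2_liability = 0.5, rg = 0,
                      n_discovery = 500L, n_cases = 1L, n_relatives = 0L,
                      n_controls = 200L, prevalence = 0.01,
                      seed = seed + 7919L * (i - 1L))
    eff <- simulate_effects(cfg)
    disc <- simulate_genotypes(cfg, "discovery")
    ss <- simulate_discovery_sumstats(disc, eff, cfg)
    tgt <- simulate_genotypes(cfg, "target-founder", n = 200L)
    y <- simulate_target_trait(tgt, eff, cfg)
    sc <- score_and_scan(tgt, ss, y)
    fixed_rej[i] <- sc$scan$p_value[sc$scan$threshold == 1] < alpha
    best_rej[i] <- nrow(sc$best) > 0 && sc$best$p_value < alpha
  }
  list(fixed_rate = mean(fixed_rej), best_rate = mean(best_rej),
       n_reps = n_reps, rejections = sum(fixed_rej))
}

#' Power of the PRS-trait association under a moderate genetic correlation
#'
#' Simulates, per seed, a 20,000-variant LD-blocked panel, a 2,000-sample
#' discovery GWAS with `h2 = 0.5`, and a 1,000-sample target cohort whose
#' trait has genetic correlation `rg = 0.5` with the discovery trait, then
#' scans the threshold grid against the trait, reporting -- as the study's
#' own procedure does -- the p-value at the best cutoff (maximum variance
#' explained), alongside the pre-fixed `P_T <= 1` fit.
#'
#' @param n_seeds number of independent simulations (default 10).
#' @param seed base seed.
#' @param n_variants,n_discovery,n_target problem sizes.
#' @return list with `p_values` (best-cutoff), `p_fixed` (at `P_T <= 1`),
#'   `n_significant` (best-cutoff p < 0.05), `r2` (best-cutoff variance
#'   explained), `n_seeds`.
#' @export
prs_power_check <- function(n_seeds = 10L, seed = 1L, n_variants = 20000L,
                            n_discovery = 2000L, n_target = 1000L) {
  p <- p_fixed <- r2 <- numeric(n_seeds)
  for (i in seq_len(n_seeds)) {
    cfg <- sim_config(n_variants = n_variants, block_size = 50L,
                      within_block_rho = 0.8, prop_causal = 0.1,
                      h2_discovery = 0.5, h2_liability = 0.5, rg = 0.5,
                      n_discovery = n_discovery, n_cases = 1L,
                      n_relatives = 0L, n_controls = n_target,
                      prevalence = 0.01, seed = seed + 104729L * (i - 1L))
    eff <- simulate_effects(cfg)
    disc <- simulate_genotypes(cfg, "discovery")
    ss <- simulate_discovery_sumstats(disc, eff, cfg)
    rm(disc); gc(verbose = FALSE)
    tgt <- simulate_genotypes(cfg, "target-founder", n = n_target)
    y <- simulate_target_trait(tgt, eff, cfg)
    sc <- score_and_scan(tgt, ss, y)
    p[i] <- sc$best$p_value
    r2[i] <- sc$best$variance_explained
    p_fixed[i] <- sc$scan$p_value[sc$scan$threshold == 1]
    rm(tgt); gc(verbose = FALSE)
  }
  list(p_values = p, p_fixed = p_fixed, n_significant = sum(p < 0.05),
       r2 = r2, n_seeds = n_seeds)
}

#' Recovery of the case > relative > control mean-score ordering
#'
#' Simulates, per seed, a liability-threshold target cohort (cases,
#' unaffected siblings, screened controls) under a perfect genetic
#' correlation (`rg = 1`) and strong heritability (0.8 on both sides),
#' scores everyone with the discovery-trained `P_T <= 1` PRS, and checks
#' whether the group means order SCZ > FR > HC.
#'
#' @param n_seeds number of independent simulations (default 20).
#' @param seed base seed.
#' @param n_variants,n_discovery problem sizes (defaults 2,000 / 1,000).
#' @param prevalence disease prevalence for the ascertainment (default 0.1,
#'   a desk-scale rate that keeps rejection sampling light).
#' @return list with `n_ordered`, `orderings` (per-seed logical), and the
#'   per-seed group means.
#' @export
prs_ordering_check <- function(n_seeds = 20L, seed = 1L, n_variants = 2000L,
                               n_discovery = 1000L, prevalence = 0.1) {
  ok <- logical(n_seeds)
  means <- matrix(NA_real_, n_seeds, 3L,
                  dimnames = list(NULL, c("HC", "FR", "SCZ")))
  for (i in seq_len(n_seeds)) {
    cfg <- sim_config(n_variants = n_variants, block_size = 50L,
                      within_block_rho = 0.8, prop_causal = 0.1,
                      h2_discovery = 0.8, h2_liability = 0.8, rg = 1,
                      n_discovery = n_discovery, n_cases = 130L,
                      n_relatives = 56L, n_controls = 146L,
                      prevalence = prevalence,
                      seed = seed + 15485863L * (i - 1L))
    eff <- simulate_effects(cfg)
    disc <- simulate_genotypes(cfg, "discovery")
    ss <- simulate_discovery_sumstats(disc, eff, cfg)
    coh <- simulate_target_cohort(cfg, eff)
    h <- harmonize_alleles(ss, coh$panel$variants)
    s <- prs_score(coh$panel, h,
                   h$variant_id[!startsWith(h$match_type, "excluded")])
    mg <- tapply(s, coh$group, mean)
    means[i, ] <- mg[c("HC", "FR", "SCZ")]
    ok[i] <- mg[["SCZ"]] > mg[["FR"]] && mg[["FR"]] > mg[["HC"]]
  }
  list(n_ordered = sum(ok), orderings = ok, group_means = means,
       n_seeds = n_seeds)
}

#' Monotonicity of variance explained in the discovery sample size
#'
#' For each seed, trains the PRS on discovery cohorts of increasing size
#' (default 500 / 2,000 / 8,000) against a fixed 4,000-variant architecture
#' and a fixed 1,000-sample target cohort, and records the variance the
#' `P_T <= 1` score explains in the correlated target trait. Larger discovery
#' GWASs estimate the weights better, so variance explained should increase.
#'
#' @param n_seeds number of seeds (default 5).
#' @param seed base seed.
#' @param n_grid increasing discovery sizes.
#' @param n_variants,n_target problem sizes.
#' @return list with `r2` (seeds x sizes matrix), `n_monotone` (seeds with
#'   strictly increasing variance explained), `n_seeds`.
#' @export
prs_monotonicity_check <- function(n_seeds = 5L, seed = 1L,
                                   n_grid = c(500L, 2000L, 8000L),
                                   n_variants = 4000L, n_target = 1000L) {
  r2 <- matrix(NA_real_, n_seeds, length(n_grid),
               dimnames = list(NULL, paste0("n", n_grid)))
  for (i in seq_len(n_seeds)) {
    base_seed <- seed + 32452843L * (i - 1L)
    for (j in seq_along(n_grid)) {
      cfg <- sim_config(n_variants = n_variants, block_size = 50L,
                        within_block_rho = 0.8, prop_causal = 0.1,
                        h2_discovery = 0.5, h2_liability = 0.5, rg = 0.5,
                        n_discovery = n_grid[j], n_cases = 1L,
                        n_relatives = 0L, n_controls = n_target,
                        prevalence = 0.01, seed = base_seed)
      eff <- simulate_effects(cfg)
      disc <- simulate_genotypes(cfg, "discovery")
      ss <- simulate_discovery_sumstats(disc, eff, cfg)
      rm(disc); gc(verbose = FALSE)
      tgt <- simulate_genotypes(cfg, "target-founder", n = n_target)
      y <- simulate_target_trait(tgt, eff, cfg)
      h <- harmonize_alleles(ss, tgt$variants)
      s <- prs_score(tgt, h,
                     h$variant_id[!startsWith(h$match_type, "excluded")])
      r2[i, j] <- fit_linear(y, s)$variance_explained
    }
  }
  mono <- apply(r2, 1L, function(x) all(diff(x) > 0))
  list(r2 = r2, n_monotone = sum(mono), n_seeds = n_seeds)
}
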