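# Synthetic-data generator: variant panel, true effects, genotypes.
#
# Haplotypes are drawn per LD block from a Gaussian copula with AR(1)
# correlation, thresholded at each variant's allele-frequency quantile; a
# diploid dosage is the sum of two independent haplotypes, so founder
# genotypes satisfy Hardy-Weinberg equilibrium by construction.

# Deterministic variant metadata shared by all generator ops: ids, chromosome
# and position layout (LD blocks never span a chromosome), allele pairs with
# a realistic transition excess (so a small fraction is strand-ambiguous),
# per-variant minor-allele frequencies and imputation-quality scores.
variant_frame <- function(cfg) {
  validate_sim_config(cfg)
  m <- cfg$n_variants
  bs <- cfg$block_size
  n_blocks <- ceiling(m / bs)
  set.seed(sim_seed(cfg, 101))
  n_chrom <- min(22L, n_blocks)
  block_chrom <- sort(rep_len(seq_len(n_chrom), n_blocks))
  chrom <- as.character(block_chrom[ceiling(seq_len(m) / bs)])
  pos <- integer(m)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    pos[i] <- seq_along(i) * 5000L
  }
  transitions <- matrix(c("A", "G", "G", "A", "C", "T", "T", "C"), ncol = 2, byrow = TRUE)
  transversions <- matrix(c("A", "C", "C", "A", "A", "T", "T", "A",
                            "C", "G", "G", "C", "G", "T", "T", "G"),
                          ncol = 2, byrow = TRUE)
  is_ts <- runif(m) < 0.85
  pick_ts <- sample.int(4L, m, replace = TRUE)
  pick_tv <- sample.int(8L, m, replace = TRUE)
  ref <- ifelse(is_ts, transitions[pick_ts, 1], transversions[pick_tv, 1])
  alt <- ifelse(is_ts, transitions[pick_ts, 2], transversions[pick_tv, 2])
  maf <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  info <- round(pmin(1, stats::rbeta(m, 30, 1)), 4)
  data.frame(variant_id = sprintf("var%06d", seq_len(m)),
             chrom = chrom, pos = pos, ref = ref, alt = alt,
             info = info, maf = maf, stringsAsFactors = FALSE)
}

ar1_chol <- function(k, rho) {
  if (k == 1L || rho == 0) return(diag(k))
  chol(rho^abs(outer(seq_len(k), seq_len(k), "-")))
}

# One haplotype matrix (n_hap x m of 0/1) under the blockwise AR(1) copula.
sim_haplotypes <- function(n_hap, vf, cfg) {
  m <- nrow(vf)
  bs <- cfg$block_size
  H <- matrix(0, n_hap, m)
  thr <- qnorm(vf$maf)
  start <- 1L
  while (start <= m) {
    end <- min(start + bs - 1L, m)
    k <- end - start + 1L
    Z <- matrix(rnorm(n_hap * k), n_hap, k)
    if (cfg$within_block_rho > 0 && k > 1L)
      Z <- Z %*% ar1_chol(k, cfg$within_block_rho)
    H[, start:end] <- (Z < rep(thr[start:end], each = n_hap)) + 0
    start <- end + 1L
  }
  H
}

# Diploid dosage matrix for n unrelated individuals, built block by block by
# summing two independent haplotype draws (keeps peak memory at one block).
sim_dosages <- function(n, vf, cfg) {
  m <- nrow(vf)
  bs <- cfg$block_size
  D <- matrix(0, n, m)
  thr <- qnorm(vf$maf)
  start <- 1L
  while (start <= m) {
    end <- min(start + bs - 1L, m)
    k <- end - start + 1L
    R <- if (cfg$within_block_rho > 0 && k > 1L)
      ar1_chol(k, cfg$within_block_rho) else NULL
    tcol <- rep(thr[start:end], each = n)
    acc <- matrix(0, n, k)
    for (h in 1:2) {
      Z <- matrix(rnorm(n * k), n, k)
      if (!is.null(R)) Z <- Z %*% R
      acc <- acc + (Z < tcol)
    }
    D[, start:end] <- acc
    start <- end + 1L
  }
  D
}

#' Simulate true per-variant effect sizes
#'
#' Draws a spike-and-slab architecture: a fraction `prop_causal` of variants
#' receives a bivariate-normal effect pair (discovery trait, disease
#' liability) with correlation `rg`; all other variants have both effects
#' exactly zero. Effects are scaled so that, under linkage equilibrium and
#' Hardy-Weinberg genotype frequencies at the generated allele frequencies,
#' the genetic variance of the discovery trait equals `h2_discovery` and that
#' of the liability equals `h2_liability` (phenotype construction additionally
#' standardizes the realized genetic values, making the in-cohort
#' heritabilities exact).
#'
#' @param config a [sim_config()].
#' @param stream integer sub-stream index; different streams draw independent
#'   effect vectors over the same variant panel (default 0).
#' @return data.frame of class `true_effects` with columns `variant_id`,
#'   `causal`, `beta_discovery`, `beta_liability`.
#' @export
#' @examples
#' eff <- simulate_effects(sim_config(n_variants = 500, seed = 1))
#' cor(eff$beta_discovery[eff$causal], eff$beta_liability[eff$causal])
simulate_effects <- function(config, stream = 0L) {
  validate_sim_config(config)
  vf <- variant_frame(config)
  m <- config$n_variants
  n_causal <- max(1L, round(config$prop_causal * m))
  set.seed(sim_seed(config, 211 + 13 * stream))
  causal_idx <- sort(sample.int(m, n_causal))
  z1 <- rnorm(n_causal)
  z2 <- config$rg * z1 + sqrt(1 - config$rg^2) * rnorm(n_causal)
  b1 <- b2 <- numeric(m)
  b1[causal_idx] <- z1
  b2[causal_idx] <- z2
  w <- 2 * vf$maf * (1 - vf$maf)  # per-variant genotypic variance under HWE
  scale_to <- function(b, h2) {
    v <- sum(w * b^2)
    if (v > 0 && h2 > 0) b * sqrt(h2 / v) else b * 0
  }
  out <- data.frame(variant_id = vf$variant_id,
                    causal = seq_len(m) %in% causal_idx,
                    beta_discovery = scale_to(b1, config$h2_discovery),
                    beta_liability = scale_to(b2, config$h2_liability))
  class(out) <- c("true_effects", "data.frame")
  out
}

#' Simulate genotype dosage panels
#'
#' Generates a cohort of unrelated individuals (`role = "discovery"` or
#' `"target-founder"`) or, for `role = "target-offspring"`, sibling pairs
#' produced by Mendelian transmission from shared simulated parental
#' haplotypes (expected genotypic correlation 0.5 between siblings).
#'
#' @param config a [sim_config()].
#' @param role one of `"discovery"`, `"target-founder"`, `"target-offspring"`.
#' @param n number of individuals (or sibling pairs for offspring); defaults
#'   to `n_discovery`, `n_controls`, or `n_cases` respectively.
#' @return a [dosage_panel()] for founder roles; for `"target-offspring"`, a
#'   list with panels `sib1` and `sib2` (pair `i` of each panel are siblings).
#' @export
simulate_genotypes <- function(config,
                               role = c("discovery", "target-founder", "target-offspring"),
                               n = NULL) {
  role <- match.arg(role)
  validate_sim_config(config)
  vf <- variant_frame(config)
  meta <- vf[, c("variant_id", "chrom", "pos", "ref", "alt", "info")]
  if (role == "discovery") {
    n <- if (is.null(n)) config$n_discovery else as.integer(n)
    set.seed(sim_seed(config, 307))
    return(dosage_panel(meta, sprintf("disc%05d", seq_len(n)),
                        sim_dosages(n, vf, config)))
  }
  if (role == "target-founder") {
    n <- if (is.null(n)) config$n_controls else as.integer(n)
    set.seed(sim_seed(config, 311))
    return(dosage_panel(meta, sprintf("fnd%05d", seq_len(n)),
                        sim_dosages(n, vf, config)))
  }
  n <- if (is.null(n)) config$n_cases else as.integer(n)
  set.seed(sim_seed(config, 313))
  kids <- sim_sib_pairs(n, vf, config)
  list(sib1 = dosage_panel(meta, sprintf("sibA%05d", seq_len(n)), kids$child1),
       sib2 = dosage_panel(meta, sprintf("sibB%05d", seq_len(n)), kids$child2))
}

# Two full siblings per family: each child inherits, independently per
# variant, one of the two maternal and one of the two paternal haplotypes.
sim_sib_pairs <- function(n_fam, vf, cfg) {
  mh1 <- sim_haplotypes(n_fam, vf, cfg); mh2 <- sim_haplotypes(n_fam, vf, cfg)
  fh1 <- sim_haplotypes(n_fam, vf, cfg); fh2 <- sim_haplotypes(n_fam, vf, cfg)
  m <- nrow(vf)
  draw_child <- function() {
    cm <- matrix(runif(n_fam * m) < 0.5, n_fam, m)
    cf <- matrix(runif(n_fam * m) < 0.5, n_fam, m)
    mh1 * cm + mh2 * (1 - cm) + fh1 * cf + fh2 * (1 - cf)
  }
  list(child1 = draw_child(), child2 = draw_child())
}

#' Liability threshold for a given prevalence
#'
#' Under the liability-threshold model, disease occurs when a standard-normal
#' liability exceeds the upper `prevalence` quantile.
#'
#' @param prevalence population prevalence in `(0, 1)`.
#' @return the threshold `qnorm(1 - prevalence)`.
#' @export
#' @examples
#' liability_threshold(0.5) # 0
liability_threshold <- function(prevalence) {
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must lie in (0, 1)")
  qnorm(1 - prevalence)
}
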