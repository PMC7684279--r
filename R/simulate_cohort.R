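# Discovery summary statistics, ascertained target cohort, phenotypes and
# on-disk fixture sets.

clamp_p <- function(p) pmin(pmax(p, .Machine$double.xmin), 1)

# Vectorized per-SNP marginal linear regression (slope, two-sided t-test p).
marginal_linear <- function(D, y) {
  n <- length(y)
  xm <- colMeans(D)
  ym <- mean(y)
  Sxy <- as.vector(crossprod(D, y)) - n * xm * ym
  Sxx <- colSums(D * D) - n * xm^2
  Syy <- sum(y^2) - n * ym^2
  mono <- Sxx <= 1e-12
  beta <- ifelse(mono, 0, Sxy / pmax(Sxx, 1e-12))
  rss <- pmax(Syy - beta * Sxy, 0)
  se <- sqrt(rss / (n - 2) / pmax(Sxx, 1e-12))
  tval <- ifelse(mono | se == 0, 0, beta / se)
  p <- ifelse(mono, 1, 2 * pt(-abs(tval), df = n - 2))
  list(weight = beta, p_value = clamp_p(p), monomorphic = mono)
}

# Per-SNP marginal logistic regression via glm.fit (weights are log odds
# ratios, Wald p). Only used for binary discovery traits.
marginal_logistic <- function(D, y) {
  m <- ncol(D)
  beta <- numeric(m); p <- numeric(m)
  mono <- apply(D, 2L, function(x) var(x) <= 1e-12)
  for (j in seq_len(m)) {
    if (mono[j]) { beta[j] <- 0; p[j] <- 1; next }
    X <- cbind(1, D[, j])
    fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
    co <- fit$coefficients[2]
    W <- fit$weights
    XtWX <- crossprod(X * sqrt(W))
    se <- sqrt(diag(solve(XtWX)))[2]
    beta[j] <- co
    p[j] <- 2 * pnorm(-abs(co / se))
  }
  list(weight = beta, p_value = clamp_p(p), monomorphic = mono)
}

#' Simulate discovery GWAS summary statistics
#'
#' Builds a discovery phenotype from the true effects (standardized genetic
#' value plus Gaussian environment for continuous traits; a logistic link on
#' the genetic value for binary traits) and regresses it on each variant's
#' dosage marginally, one SNP at a time, exactly as a single-SNP GWAS does.
#' Weights are therefore internally consistent with their p-values.
#' Monomorphic variants get weight 0 and p-value 1 and are flagged.
#'
#' @param panel discovery [dosage_panel()] from [simulate_genotypes()].
#' @param effects a `true_effects` frame from [simulate_effects()].
#' @param config the [sim_config()] used to generate both.
#' @param stream integer sub-stream index, lets several independent phenotype
#'   realizations be drawn for the same panel (default 0).
#' @return a `data.frame` in the summary-statistics schema consumed by
#'   [read_summary_stats()]: `variant_id`, `chromosome`, `position`,
#'   `effect_allele` (the ALT allele), `other_allele`, `weight` (beta for
#'   continuous traits, log odds ratio for binary), `p_value`, `eaf`, `info`,
#'   plus a `monomorphic` flag. The trait type is carried in
#'   `attr(, "trait_type")`.
#' @export
simulate_discovery_sumstats <- function(panel, effects, config, stream = 0L) {
  stopifnot(inherits(panel, "dosage_panel"))
  validate_sim_config(config)
  if (!identical(panel$variants$variant_id, effects$variant_id))
    stop("panel and effects describe different variant sets")
  D <- panel$dosages
  n <- nrow(D)
  set.seed(sim_seed(config, 401 + 7 * stream))
  g <- as.vector(D %*% effects$beta_discovery)
  gs <- if (sd(g) > 0) as.vector(scale(g)) else rep(0, n)
  h2 <- config$h2_discovery
  if (config$trait_type == "continuous") {
    y <- sqrt(h2) * gs + rnorm(n, 0, sqrt(1 - h2))
    st <- marginal_linear(D, y)
  } else {
    # latent-logistic scaling: genetic share of latent variance equals h2
    k <- if (h2 > 0) sqrt(h2 / (1 - h2) * pi^2 / 3) else 0
    y <- rbinom(n, 1L, plogis(k * gs))
    if (length(unique(y)) < 2L) stop("degenerate binary discovery trait (one class)")
    st <- marginal_logistic(D, y)
  }
  out <- data.frame(variant_id = panel$variants$variant_id,
                    chromosome = panel$variants$chrom,
                    position = panel$variants$pos,
                    effect_allele = panel$variants$alt,
                    other_allele = panel$variants$ref,
                    weight = st$weight,
                    p_value = st$p_value,
                    eaf = colMeans(D) / 2,
                    info = panel$variants$info,
                    monomorphic = st$monomorphic,
                    stringsAsFactors = FALSE)
  attr(out, "trait_type") <- config$trait_type
  out
}

#' Simulate an ascertained liability-threshold target cohort
#'
#' Generates cases (liability above the prevalence threshold), one unaffected
#' full sibling per case family for the first `n_relatives` families, and
#' unaffected controls. Liability is the standardized liability-side genetic
#' value (variance `h2_liability`, standardized against an internal founder
#' reference sample) plus independent Gaussian environment. Families are
#' rejection-sampled in batches until the configured group sizes are reached.
#'
#' @param config a [sim_config()].
#' @param effects optional `true_effects`; simulated from `config` if omitted.
#' @return an object of class `target_cohort`: a list with the combined
#'   [dosage_panel()] (`panel`), the `group` factor (`SCZ`/`FR`/`HC`), the
#'   realized `liability`, the standardized discovery-trait genetic value
#'   `g_discovery`, the liability `threshold`, and the `config`.
#' @export
simulate_target_cohort <- function(config, effects = NULL) {
  validate_sim_config(config)
  if (is.null(effects)) effects <- simulate_effects(config)
  vf <- variant_frame(config)
  meta <- vf[, c("variant_id", "chrom", "pos", "ref", "alt", "info")]
  b_l <- effects$beta_liability
  b_d <- effects$beta_discovery
  h2l <- config$h2_liability
  thr <- liability_threshold(config$prevalence)
  set.seed(sim_seed(config, 601))

  # population standardization of genetic values from a founder reference
  Gref <- sim_dosages(400L, vf, config)
  std_par <- function(b) {
    g <- as.vector(Gref %*% b)
    c(mu = mean(g), s = sd(g))
  }
  pl <- std_par(b_l); pd <- std_par(b_d)
  g_liab <- function(G) {
    if (pl["s"] > 0 && h2l > 0)
      sqrt(h2l) * (as.vector(G %*% b_l) - pl["mu"]) / pl["s"]
    else rep(0, nrow(G))
  }
  g_disc <- function(G) {
    if (pd["s"] > 0) (as.vector(G %*% b_d) - pd["mu"]) / pd["s"] else rep(0, nrow(G))
  }
  env_sd <- sqrt(1 - h2l)

  # controls: founders screened to be unaffected
  ctrl_d <- NULL; ctrl_l <- numeric(0)
  guard <- 0L
  while (length(ctrl_l) < config$n_controls) {
    nb <- max(config$n_controls, 200L)
    G <- sim_dosages(nb, vf, config)
    li <- g_liab(G) + rnorm(nb, 0, env_sd)
    keep <- li <= thr
    ctrl_d <- rbind(ctrl_d, G[keep, , drop = FALSE])
    ctrl_l <- c(ctrl_l, li[keep])
    guard <- guard + 1L
    if (guard > 50L)
      stop("could not assemble ", config$n_controls, " unaffected controls; ",
           "prevalence ", config$prevalence, " leaves too few unaffected")
  }
  ctrl_d <- ctrl_d[seq_len(config$n_controls), , drop = FALSE]
  ctrl_l <- ctrl_l[seq_len(config$n_controls)]

  # case families: affected child1 is the case; its sibling is the candidate
  # relative, usable only if unaffected. Collect families until there are
  # enough cases AND enough case families with an unaffected sibling, so each
  # relative is the sibling of an included case.
  need_cases <- config$n_cases; need_rels <- config$n_relatives
  fam_case_d <- fam_sib_d <- NULL
  fam_case_l <- fam_sib_l <- numeric(0)
  fam_has_sib <- logical(0)
  # batch size balances rejection-sampling throughput against the memory of
  # twelve n x m family matrices
  batch <- as.integer(min(2000L, max(100L, floor(1e7 / nrow(vf)))))
  max_batches <- ceiling(need_cases / (config$prevalence * batch)) * 8L + 10L
  b <- 0L
  enough <- function() {
    length(fam_case_l) >= need_cases && sum(fam_has_sib) >= need_rels
  }
  while (need_cases > 0L && !enough()) {
    b <- b + 1L
    if (b > max_batches)
      stop("liability threshold for prevalence ", config$prevalence,
           " unreachable: exhausted ", max_batches, " batches of ", batch,
           " families while ascertaining cases")
    kids <- sim_sib_pairs(batch, vf, config)
    l1 <- g_liab(kids$child1) + rnorm(batch, 0, env_sd)
    aff <- which(l1 > thr)
    if (!length(aff)) next
    l2 <- g_liab(kids$child2[aff, , drop = FALSE]) + rnorm(length(aff), 0, env_sd)
    fam_case_d <- rbind(fam_case_d, kids$child1[aff, , drop = FALSE])
    fam_case_l <- c(fam_case_l, l1[aff])
    fam_sib_d <- rbind(fam_sib_d, kids$child2[aff, , drop = FALSE])
    fam_sib_l <- c(fam_sib_l, l2)
    fam_has_sib <- c(fam_has_sib, l2 <= thr)
  }
  if (need_cases > 0L) {
    # families whose sibling is unaffected supply the relatives first
    with_sib <- which(fam_has_sib)[seq_len(need_rels)]
    others <- setdiff(seq_along(fam_case_l), with_sib)
    pick <- c(with_sib, others)[seq_len(need_cases)]
    case_d <- fam_case_d[pick, , drop = FALSE]
    case_l <- fam_case_l[pick]
    rel_d <- fam_sib_d[with_sib, , drop = FALSE]
    rel_l <- fam_sib_l[with_sib]
  } else {
    case_d <- rel_d <- matrix(0, 0, nrow(vf))
    case_l <- rel_l <- numeric(0)
  }
  if (need_rels == 0L) { rel_d <- matrix(0, 0, nrow(vf)); rel_l <- numeric(0) }

  dos <- rbind(case_d, rel_d, ctrl_d)
  samples <- c(sprintf("scz%04d", seq_len(need_cases)),
               sprintf("fr%04d", seq_len(need_rels)),
               sprintf("hc%04d", seq_len(config$n_controls)))
  group <- factor(rep(c("SCZ", "FR", "HC"),
                      c(need_cases, need_rels, config$n_controls)),
                  levels = c("HC", "FR", "SCZ"))
  panel <- dosage_panel(meta, samples, dos)
  structure(list(panel = panel,
                 group = group,
                 liability = c(case_l[seq_len(need_cases)],
                               rel_l[seq_len(need_rels)], ctrl_l),
                 g_discovery = g_disc(dos),
                 threshold = thr,
                 config = config),
            class = "target_cohort")
}

#' @export
print.target_cohort <- function(x, ...) {
  cat(sprintf("<target_cohort> %s (threshold %.3f)\n",
              paste(sprintf("%s=%d", levels(x$group), table(x$group)), collapse = " "),
              x$threshold))
  invisible(x)
}

# Group-level demographic distributions used by the phenotype generator
# (means/SDs and male fractions of a mixed case/relative/control cohort).
target_demographics <- function() {
  data.frame(group = c("HC", "FR", "SCZ"),
             age_mean = c(37.2, 56.8, 42.9), age_sd = c(14.1, 15.6, 13.1),
             male_frac = c(97 / 146, 18 / 56, 50 / 130),
             edu_mean = c(16.1, 12.8, 12.6), edu_sd = c(2.4, 2.1, 2.2),
             stringsAsFactors = FALSE)
}

#' Simulate target phenotypes
#'
#' Builds the per-individual phenotype table for a simulated target cohort:
#' diagnosis group from the liability ascertainment, demographics (age, sex,
#' education) from group-level distributions, and the smoking variables from
#' the discovery-trait genetic value through the configured links --
#' ever/never smoking via a logistic link, age at daily-smoking initiation
#' log-normal with a log-scale genetic shift, cigarettes per day as an
#' over-dispersed (negative-binomial) count, and current/former status via a
#' logistic link. Smoker-only fields are missing for never-smokers; onset age
#' is present for cases only.
#'
#' @param cohort a `target_cohort` from [simulate_target_cohort()].
#' @param config a [sim_config()]; defaults to the cohort's own.
#' @return a `data.frame` of class `phenotype_table` with columns `sample_id`,
#'   `group`, `age`, `sex`, `education`, `ever_smoker`, `age_initiation`,
#'   `cpd`, `current_smoker`, `onset_age`.
#' @export
simulate_phenotypes <- function(cohort, config = cohort$config) {
  stopifnot(inherits(cohort, "target_cohort"))
  validate_sim_config(config)
  sp <- config$smoking_params
  gd <- cohort$g_discovery
  grp <- as.character(cohort$group)
  n <- length(gd)
  dem <- target_demographics()
  di <- match(grp, dem$group)
  set.seed(sim_seed(config, 503))
  age <- round(pmin(pmax(rnorm(n, dem$age_mean[di], dem$age_sd[di]), 18), 85), 1)
  sex <- ifelse(runif(n) < dem$male_frac[di], "M", "F")
  education <- round(pmin(pmax(rnorm(n, dem$edu_mean[di], dem$edu_sd[di]), 9), 21), 1)
  ever <- runif(n) < plogis(qlogis(sp$ever_rate) + sp$ever_beta * gd)
  age_init <- exp(sp$init_meanlog + sp$init_beta * gd +
                  rnorm(n, 0, sp$init_sdlog))
  age_init <- round(pmin(pmax(age_init, 12), age), 1)
  cpd <- rnbinom(n, size = sp$cpd_size, mu = sp$cpd_mu * exp(sp$cpd_beta * gd)) + 1L
  current <- runif(n) < plogis(qlogis(sp$current_rate) + sp$current_beta * gd)
  onset <- round(pmin(pmax(rnorm(n, 26.9, 10.6), 13), age), 1)
  out <- data.frame(sample_id = cohort$panel$samples,
                    group = grp,
                    age = age, sex = sex, education = education,
                    ever_smoker = ever,
                    age_initiation = ifelse(ever, age_init, NA_real_),
                    cpd = ifelse(ever, cpd, NA_integer_),
                    current_smoker = ifelse(ever, current, NA),
                    onset_age = ifelse(grp == "SCZ", onset, NA_real_),
                    stringsAsFactors = FALSE)
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Write a complete simulated fixture set to disk
#'
#' Simulates one discovery cohort, draws independent true-effect vectors and
#' phenotype realizations for each configured smoking trait, computes marginal
#' summary statistics per trait, simulates the ascertained target cohort
#' (from the first trait's effects, by convention the age-at-initiation
#' trait), and writes everything in the formats the pipeline reads: one
#' summary-statistics file per trait, the target dosages in both dialects
#' (dosage-tsv and VCF), the phenotype table, the configuration, and a
#' manifest with MD5 checksums. Re-running with the same config reproduces
#' byte-identical files.
#'
#' @param config a [sim_config()].
#' @param output_dir directory to write into (created if needed).
#' @param traits named character vector mapping trait name to
#'   `"continuous"`/`"binary"`; default the four smoking phenotypes.
#' @return invisibly, the manifest `data.frame` (file, md5, bytes).
#' @export
generate_fixture_set <- function(config, output_dir,
                                 traits = c(age_initiation = "continuous",
                                            initiation = "binary",
                                            quantity = "continuous",
                                            cessation = "binary")) {
  validate_sim_config(config)
  stopifnot(length(traits) >= 1, all(traits %in% c("continuous", "binary")))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  disc <- simulate_genotypes(config, "discovery")
  files <- character(0)
  eff1 <- NULL
  for (i in seq_along(traits)) {
    cfg_i <- config
    cfg_i$trait_type <- unname(traits[i])
    eff <- simulate_effects(cfg_i, stream = i - 1L)
    if (i == 1L) eff1 <- eff
    ss <- simulate_discovery_sumstats(disc, eff, cfg_i, stream = i - 1L)
    f <- file.path(output_dir, paste0("sumstats_", names(traits)[i], ".tsv"))
    write_summary_stats(ss, f)
    files <- c(files, f)
  }
  cohort <- simulate_target_cohort(config, eff1)
  pheno <- simulate_phenotypes(cohort, config)
  f_tsv <- file.path(output_dir, "target_dosages.tsv")
  f_vcf <- file.path(output_dir, "target_dosages.vcf")
  f_ph <- file.path(output_dir, "phenotypes.tsv")
  f_cfg <- file.path(output_dir, "config.yaml")
  write_dosages(cohort$panel, f_tsv, dialect = "dosage-tsv")
  write_dosages(cohort$panel, f_vcf, dialect = "vcf-dosage")
  write_phenotypes(pheno, f_ph)
  yaml::write_yaml(unclass(config), f_cfg)
  files <- c(files, f_tsv, f_vcf, f_ph, f_cfg)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         bytes = file.size(files),
                         stringsAsFactors = FALSE)
  data.table::fwrite(manifest, file.path(output_dir, "manifest.tsv"), sep = "\t")
  invisible(manifest)
}
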