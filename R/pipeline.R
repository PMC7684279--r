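# End-to-end orchestration: simulate (or read) -> QC -> harmonize -> prune ->
# score -> associate/survive, driven by a YAML-compatible config file.

pipeline_defaults <- function() {
  list(qc = list(maf_min = 0.01, hwe_alpha = 1e-6, info_min = 0.9,
                 drop_ambiguous = TRUE, drop_chroms = c("Y", "MT")),
       prune = list(r2_max = 0.25, window_snps = 200L, step_snps = 50L,
                    priority = "order"),
       grid = default_grid(),
       analyses = list(
         list(name = "age_initiation", trait = "age_initiation",
              outcome = "age_initiation", model = "linear",
              subset = "ever", log_outcome = TRUE),
         list(name = "initiation", trait = "initiation",
              outcome = "ever_smoker", model = "logistic", subset = "all"),
         list(name = "quantity", trait = "quantity",
              outcome = "cpd", model = "linear", subset = "ever"),
         list(name = "cessation", trait = "cessation",
              outcome = "current_smoker", model = "logistic", subset = "ever"),
         list(name = "diagnosis3", trait = "age_initiation",
              outcome = "diagnosis3", model = "linear", subset = "all"),
         list(name = "diagnosis2", trait = "age_initiation",
              outcome = "diagnosis2", model = "logistic", subset = "no_fr")))
}

read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  def <- pipeline_defaults()
  for (k in names(def))
    config[[k]] <- if (is.null(config[[k]])) def[[k]] else
      if (is.list(def[[k]]) && k != "analyses" && k != "grid")
        modifyList(def[[k]], config[[k]]) else config[[k]]
  if (is.null(config$simulate) && is.null(config$inputs))
    stop("config needs either a 'simulate' block or an 'inputs' block")
  config
}

analysis_outcome <- function(spec, pheno) {
  sub <- switch(spec$subset %||% "all",
                all = rep(TRUE, nrow(pheno)),
                ever = pheno$ever_smoker %in% TRUE,
                no_fr = pheno$group != "FR",
                stop("unknown subset: ", spec$subset))
  y <- switch(spec$outcome,
              diagnosis3 = as.numeric(factor(pheno$group, c("HC", "FR", "SCZ"))) - 1,
              diagnosis2 = as.numeric(pheno$group == "SCZ"),
              {
                v <- pheno[[spec$outcome]]
                if (is.null(v)) stop("unknown phenotype column: ", spec$outcome)
                if (is.logical(v)) as.numeric(v) else as.numeric(v)
              })
  if (isTRUE(spec$log_outcome)) y <- log(y)
  list(subset = sub, y = y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full PRS pipeline
#'
#' Executes the stages in order -- obtain inputs (simulating a fixture set
#' when the config has a `simulate` block, otherwise reading the files named
#' under `inputs`), variant QC, per-trait allele harmonization, LD pruning,
#' threshold scoring, association scans, the survival comparison of
#' initiation age, and the late-initiation analysis -- writing per-stage
#' artifacts, a timestamped log, a machine-readable stage-count table and a
#' checksum manifest into `output_dir`. Identical config and seed reproduce
#' identical result tables.
#'
#' @param config path to a YAML config or an equivalent named list. Top-level
#'   keys: `simulate` (any [sim_config()] fields) or `inputs`
#'   (`sumstats` named list of paths, `dosages`, `dosage_dialect`,
#'   `phenotypes`), plus optional `qc`, `prune`, `grid`, `analyses`,
#'   `seed`, `output_dir`.
#' @param output_dir output directory (overrides the config; required if the
#'   config has none).
#' @param seed integer; overrides the config / simulation seed.
#' @return invisibly, a list with the scan results per analysis, the survival
#'   and late-initiation results, stage counts, and the output manifest.
#' @export
run_pipeline <- function(config, output_dir = NULL, seed = NULL) {
  cfg <- read_pipeline_config(config)
  out <- output_dir %||% cfg$output_dir
  if (is.null(out)) stop("no output directory (config 'output_dir' or argument)")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  # validate thresholds before any compute
  qc_thr <- do.call(qc_thresholds, cfg$qc)
  pr_cfg <- do.call(prune_config, cfg$prune)
  grid <- check_grid(as.numeric(cfg$grid))

  logf <- file.path(out, "run.log")
  cat("", file = logf)
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "  ", sprintf(...))
    cat(msg, "\n", file = logf, append = TRUE, sep = "")
    message(msg)
  }
  counts <- list()

  # stage: inputs
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    if (!is.null(seed)) sim_args$seed <- seed
    scfg <- do.call(sim_config, sim_args)
    say("simulate: writing fixture set (seed %d)", scfg$seed)
    fixdir <- file.path(out, "fixtures")
    generate_fixture_set(scfg, fixdir)
    traits <- c("age_initiation", "initiation", "quantity", "cessation")
    ss_paths <- setNames(file.path(fixdir, paste0("sumstats_", traits, ".tsv")), traits)
    dos_path <- file.path(fixdir, "target_dosages.tsv")
    dialect <- "dosage-tsv"
    ph_path <- file.path(fixdir, "phenotypes.tsv")
  } else {
    ss_paths <- unlist(cfg$inputs$sumstats)
    dos_path <- cfg$inputs$dosages
    dialect <- cfg$inputs$dosage_dialect %||% "dosage-tsv"
    ph_path <- cfg$inputs$phenotypes
  }
  say("read: %d summary-statistic file(s), dosages (%s), phenotypes",
      length(ss_paths), dialect)
  sumstats <- lapply(ss_paths, read_summary_stats)
  panel <- read_dosages(dos_path, dialect)
  pheno <- read_phenotypes(ph_path)
  counts$input <- nrow(panel$variants)

  # stage: QC
  qc <- variant_qc(panel, qc_thr)
  write_results(list(qc_exclusions = qc$exclusions), out)
  panel_qc <- panel_subset(panel, qc$keep)
  counts$qc <- length(qc$keep)
  say("qc: %d -> %d variants (%d excluded)", counts$input, counts$qc,
      nrow(qc$exclusions))

  # stage: prune (once, on the full QC-passing panel)
  prio <- NULL
  if (pr_cfg$priority == "p-value") {
    ss1 <- sumstats[[1]]
    prio <- ss1$p_value[match(panel_qc$variants$variant_id, ss1$variant_id)]
    prio[is.na(prio)] <- 1
  }
  kept <- prune_window(panel_qc, pr_cfg, prio)
  writeLines(kept, file.path(out, "pruned_keep.txt"))
  write_results(list(prune_report = prune_report(panel_qc, kept)), out)
  panel_pr <- panel_subset(panel_qc, kept)
  counts$pruned <- length(kept)
  say("prune: %d -> %d variants", counts$qc, counts$pruned)

  # stage: harmonize + score per trait
  profiles <- list()
  for (tr in names(ss_paths)) {
    h <- harmonize_alleles(sumstats[[tr]], panel_pr$variants)
    n_excl <- sum(startsWith(h$match_type, "excluded"))
    profiles[[tr]] <- prs_profile(panel_pr, h, grid)
    write_profile(profiles[[tr]], file.path(out, paste0("prs_", tr, ".tsv")))
    write_profile(prs_profile(panel_pr, h, grid, standardize = TRUE),
                  file.path(out, paste0("prs_", tr, "_std.tsv")))
    say("score[%s]: %d harmonized (%d excluded), snp counts %s", tr,
        nrow(h) - n_excl, n_excl,
        paste(profiles[[tr]]$snp_count, collapse = "/"))
  }
  counts$harmonized <- vapply(profiles, function(p) max(p$snp_count), numeric(1))

  # stage: association scans
  results <- list()
  for (an in cfg$analyses) {
    tr <- an$trait
    if (!tr %in% names(profiles)) stop("analysis '", an$name,
                                       "' references unknown trait: ", tr)
    oc <- analysis_outcome(an, pheno)
    prof <- profiles[[tr]]
    keep_s <- oc$subset
    sub_prof <- prof
    sub_prof$samples <- prof$samples[keep_s]
    sub_prof$scores <- prof$scores[keep_s, , drop = FALSE]
    covs <- NULL
    if (length(an$covariates)) {
      covs <- pheno[keep_s, an$covariates, drop = FALSE]
      covs$sex <- if ("sex" %in% names(covs)) as.numeric(covs$sex == "M")
    }
    sc <- scan_thresholds(sub_prof, oc$y[keep_s], model = an$model,
                          covariates = covs)
    results[[an$name]] <- sc
    write_results(setNames(list(sc$scan), paste0("scan_", an$name)), out)
    bestline <- if (nrow(sc$best))
      sprintf("best P_T <= %g: R2 = %.4f, p = %.3g", sc$best$threshold,
              sc$best$variance_explained, sc$best$p_value) else "no fit"
    say("assoc[%s]: %s", an$name, bestline)
  }

  # stage: PRS x smoking-status interaction on case status (first trait,
  # no-FR subset, score at the top of the grid)
  inter <- tryCatch({
    keep_s <- pheno$group != "FR"
    s <- profiles[[1]]$scores[keep_s, ncol(profiles[[1]]$scores)]
    it <- interaction_test(s, pheno$ever_smoker[keep_s],
                           as.numeric(pheno$group[keep_s] == "SCZ"))
    say("interaction[%s x ever/never -> diagnosis]: p = %.3g",
        names(profiles)[1], it$p_value)
    it
  }, error = function(e) { say("interaction: %s", conditionMessage(e)); NULL })
  if (!is.null(inter))
    write_results(list(interaction = data.frame(trait = names(profiles)[1],
                                                coefficient = inter$coefficient,
                                                p_value = inter$p_value,
                                                n = inter$n)), out)

  # stage: survival + late initiation + group trend on the diagnosis trait
  surv_in <- smoking_survival_input(pheno)
  surv <- tryCatch(km_logrank(surv_in$time, surv_in$event, surv_in$group),
                   error = function(e) { say("survival: %s", conditionMessage(e)); NULL })
  if (!is.null(surv)) {
    write_results(list(km_curves = surv$curves), out)
    say("survival: log-rank chi2 = %.3f (df %d), p = %.3g",
        surv$statistic, surv$df, surv$p_value)
  }
  late <- tryCatch(late_initiation_rates(pheno),
                   error = function(e) { say("late-initiation: %s", conditionMessage(e)); NULL })
  if (!is.null(late)) {
    write_results(list(late_initiation = late$rates), out)
    say("late initiation after 20: %s; adjusted p = %.3g",
        paste(sprintf("%s %.1f%%", late$rates$group, 100 * late$rates$proportion),
              collapse = ", "), late$p_value)
  }

  # bookkeeping
  sc_tab <- data.frame(stage = c("input", "qc", "pruned"),
                       variants = c(counts$input, counts$qc, counts$pruned))
  write_results(list(stage_counts = sc_tab), out)
  files <- setdiff(list.files(out, recursive = TRUE, full.names = TRUE),
                   logf)
  manifest <- data.frame(file = sub(paste0("^", out, "/?"), "", files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  data.table::fwrite(manifest, file.path(out, "manifest.tsv"), sep = "\t")
  say("done: %d files in %s", nrow(manifest), out)
  invisible(list(results = results, survival = surv, late_initiation = late,
                 interaction = inter, counts = counts, manifest = manifest))
}
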