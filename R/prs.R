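# P_T-threshold SNP-set construction and per-individual polygenic scores.

#' Default p-value threshold grid
#'
#' The eight nested P_T cutoffs scanned by the pipeline.
#'
#' @return numeric vector `c(1e-4, 1e-3, 0.01, 0.05, 0.1, 0.2, 0.5, 1)`.
#' @export
default_grid <- function() c(1e-4, 1e-3, 0.01, 0.05, 0.1, 0.2, 0.5, 1)

check_grid <- function(grid) {
  if (!length(grid) || any(!is.finite(grid)) || any(grid <= 0) || any(grid > 1) ||
      is.unsorted(grid, strictly = TRUE))
    stop("threshold grid must be strictly increasing values in (0, 1]")
  grid
}

#' Select variants per p-value threshold
#'
#' The SNP set at cutoff `t` is every harmonized variant with discovery
#' p-value `<= t`; sets are nested along the grid.
#'
#' @param harmonized data.frame from [harmonize_alleles()] (rows with
#'   `match_type` starting `excluded` are ignored).
#' @param grid strictly increasing cutoffs in `(0, 1]`.
#' @return named list (one element per cutoff, named by its value) of
#'   variant-id character vectors. Empty sets warn.
#' @export
threshold_select <- function(harmonized, grid = default_grid()) {
  check_grid(grid)
  ok <- !startsWith(harmonized$match_type, "excluded")
  h <- harmonized[ok, , drop = FALSE]
  sets <- lapply(grid, function(t) h$variant_id[h$p_value <= t])
  names(sets) <- formatC(grid, format = "g")
  empty <- lengths(sets) == 0L
  if (any(empty))
    warning("empty SNP set at cutoff(s): ",
            paste(names(sets)[empty], collapse = ", "), "; scores will be 0")
  sets
}

#' Polygenic score over one SNP set
#'
#' For each individual, the sum over the SNP set of the counted-allele dosage
#' times the aligned weight (logOR for binary discovery traits, beta for
#' continuous ones). Missing dosages are mean-imputed per variant under the
#' default policy; under `"omit"` each individual's score is rescaled by the
#' total absolute weight of their non-missing variants.
#'
#' @param panel a [dosage_panel()].
#' @param harmonized data.frame from [harmonize_alleles()].
#' @param ids SNP set (must all be present in the panel).
#' @param missing_policy `"mean_impute"` (default) or `"omit"`.
#' @return named numeric vector of scores, one per sample.
#' @export
prs_score <- function(panel, harmonized, ids,
                      missing_policy = c("mean_impute", "omit")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(panel, "dosage_panel"))
  if (!length(ids))
    return(setNames(numeric(length(panel$samples)), panel$samples))
  j <- match(ids, panel$variants$variant_id)
  if (anyNA(j))
    stop("ids not in panel: ", paste(head(ids[is.na(j)], 5), collapse = ", "))
  k <- match(ids, harmonized$variant_id)
  if (anyNA(k))
    stop("ids lacking harmonized weights: ",
         paste(head(ids[is.na(k)], 5), collapse = ", "))
  w <- harmonized$aligned_weight[k]
  if (anyNA(w)) stop("excluded (unharmonized) variants in scoring set")
  d <- panel$dosages[, j, drop = FALSE]
  if (missing_policy == "mean_impute") {
    d <- impute_mean(d)
    s <- as.vector(d %*% w)
  } else {
    obs <- !is.na(d)
    d0 <- d; d0[!obs] <- 0
    s <- as.vector(d0 %*% w)
    denom <- as.vector(obs %*% abs(w))
    total <- sum(abs(w))
    s <- ifelse(denom > 0, s * total / denom, 0)
  }
  setNames(s, panel$samples)
}

#' Polygenic score profile over a threshold grid
#'
#' Computes the raw-sum score for every individual at every cutoff (the raw
#' sum is the default; z-standardization per cutoff is available for
#' reporting) together with the SNP count per cutoff.
#'
#' @param panel a [dosage_panel()].
#' @param harmonized data.frame from [harmonize_alleles()].
#' @param grid threshold grid (default [default_grid()]).
#' @param standardize z-score each cutoff's column (default `FALSE`).
#' @param missing_policy passed to [prs_score()].
#' @return an object of class `prs_profile`: list with `samples`, `scores`
#'   (samples x cutoffs matrix), `snp_count`, `grid`, `standardized`.
#' @export
prs_profile <- function(panel, harmonized, grid = default_grid(),
                        standardize = FALSE,
                        missing_policy = c("mean_impute", "omit")) {
  missing_policy <- match.arg(missing_policy)
  sets <- suppressWarnings(threshold_select(harmonized, grid))
  scores <- vapply(sets, function(ids)
    prs_score(panel, harmonized, ids, missing_policy),
    numeric(length(panel$samples)))
  if (length(panel$samples) == 1L) scores <- matrix(scores, nrow = 1L,
                                                    dimnames = list(panel$samples, names(sets)))
  if (standardize)
    scores <- apply(scores, 2L, function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0)
  structure(list(samples = panel$samples,
                 scores = scores,
                 snp_count = lengths(sets),
                 grid = grid,
                 standardized = isTRUE(standardize)),
            class = "prs_profile")
}

#' @export
print.prs_profile <- function(x, ...) {
  cat(sprintf("<prs_profile> %d samples x %d cutoffs%s\n", length(x$samples),
              length(x$grid), if (x$standardized) " (standardized)" else ""))
  print(data.frame(cutoff = x$grid, snps = unname(x$snp_count)))
  invisible(x)
}

#' Write a PRS profile
#'
#' Tab-delimited: `sample_id` then one column per cutoff, named by its value.
#'
#' @param profile a `prs_profile`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_profile <- function(profile, path) {
  out <- data.frame(sample_id = profile$samples,
                    profile$scores, check.names = FALSE)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
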