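#' Dosage panel
#'
#' Container for a target (or discovery) genotype panel: per-variant metadata
#' plus a samples x variants matrix of alternate-allele dosages in `[0, 2]`
#' (hard genotypes 0/1/2 or fractional imputed dosages; `NA` marks missing).
#'
#' @param variants data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `ref`, `alt` and optionally `info` (imputation quality).
#' @param samples character vector of sample identifiers.
#' @param dosages numeric matrix, `length(samples)` rows by `nrow(variants)`
#'   columns; values in `[0, 2]` or `NA`.
#' @return an object of class `dosage_panel`.
#' @export
#' @examples
#' v <- data.frame(variant_id = "rs1", chrom = "1", pos = 100L,
#'                 ref = "A", alt = "G", info = 1)
#' dosage_panel(v, c("s1", "s2"), matrix(c(0, 2), 2, 1))
dosage_panel <- function(variants, samples, dosages) {
  variants <- as.data.frame(variants)
  needed <- c("variant_id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(needed, names(variants))
  if (length(miss)) stop("variant metadata lacks columns: ", paste(miss, collapse = ", "))
  if (!"info" %in% names(variants)) variants$info <- NA_real_
  dosages <- as.matrix(dosages)
  if (nrow(dosages) != length(samples) || ncol(dosages) != nrow(variants))
    stop("dosage matrix must be samples x variants (",
         length(samples), " x ", nrow(variants), "), got ",
         nrow(dosages), " x ", ncol(dosages))
  rng <- range(dosages, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < -1e-6 || rng[2] > 2 + 1e-6))
    stop("dosages outside [0, 2]: range ", rng[1], " .. ", rng[2])
  rownames(dosages) <- samples
  colnames(dosages) <- variants$variant_id
  structure(list(variants = variants, samples = as.character(samples),
                 dosages = dosages),
            class = "dosage_panel")
}

#' @export
print.dosage_panel <- function(x, ...) {
  cat(sprintf("<dosage_panel> %d samples x %d variants\n",
              length(x$samples), nrow(x$variants)))
  cat("  chromosomes:", paste(unique(x$variants$chrom), collapse = " "), "\n")
  nmiss <- sum(is.na(x$dosages))
  if (nmiss) cat(sprintf("  missing dosages: %d\n", nmiss))
  invisible(x)
}

#' Subset a dosage panel by variant id
#'
#' @param panel a [dosage_panel()].
#' @param ids variant ids to keep, in the order given.
#' @return a `dosage_panel` restricted to `ids`.
#' @export
panel_subset <- function(panel, ids) {
  stopifnot(inherits(panel, "dosage_panel"))
  idx <- match(ids, panel$variants$variant_id)
  if (anyNA(idx)) stop("ids not in panel: ", paste(head(ids[is.na(idx)], 5), collapse = ", "))
  dosage_panel(panel$variants[idx, , drop = FALSE], panel$samples,
               panel$dosages[, idx, drop = FALSE])
}

# Are all non-missing dosages whole-numbered (hard genotype calls)?
is_hard_calls <- function(panel) {
  d <- panel$dosages
  all(abs(d - round(d)) < 1e-9, na.rm = TRUE)
}
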