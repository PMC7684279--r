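# Sliding-window LD pruning on dosage correlation.

#' Pruning configuration
#'
#' @param r2_max pairwise squared-correlation ceiling in `(0, 1]`
#'   (default 0.25).
#' @param window_snps window size in SNPs (default 200).
#' @param step_snps window step in SNPs (default 50); must be in
#'   `[1, window_snps]`.
#' @param priority `"p-value"` (keep the member with the smaller discovery
#'   p-value) or `"order"` (keep the earlier variant).
#' @return object of class `prune_config`.
#' @export
prune_config <- function(r2_max = 0.25, window_snps = 200L, step_snps = 50L,
                         priority = c("p-value", "order")) {
  priority <- match.arg(priority)
  if (r2_max <= 0 || r2_max > 1) stop("r2_max must lie in (0, 1]")
  if (window_snps < 2L) stop("window_snps must be at least 2")
  if (step_snps < 1L || step_snps > window_snps)
    stop("step_snps must lie in [1, window_snps]")
  structure(list(r2_max = r2_max, window_snps = as.integer(window_snps),
                 step_snps = as.integer(step_snps), priority = priority),
            class = "prune_config")
}

#' Squared dosage correlation between two variants
#'
#' The standard pruning statistic on imputed data: the squared Pearson
#' correlation of the two dosage vectors over pairwise-complete entries.
#' If either vector has zero variance the result is 0 by convention.
#'
#' @param x,y numeric dosage vectors of equal length.
#' @return squared correlation in `[0, 1]`.
#' @export
#' @examples
#' dosage_r2(c(0, 1, 2), c(0, 1, 2)) # 1
#' dosage_r2(c(0, 1, 2), c(1, 1, 1)) # 0 (zero variance)
dosage_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("dosage vectors differ in length")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) stop("fewer than 2 complete pairs")
  x <- x[ok]; y <- y[ok]
  if (var(x) == 0 || var(y) == 0) return(0)
  cor(x, y)^2
}

# mean-impute missing dosages per variant (column)
impute_mean <- function(d) {
  if (!anyNA(d)) return(d)
  mu <- colMeans(d, na.rm = TRUE)
  mu[!is.finite(mu)] <- 0
  idx <- which(is.na(d), arr.ind = TRUE)
  d[idx] <- mu[idx[, 2L]]
  d
}

#' Sliding-window LD pruning
#'
#' Greedy windowed pruning: within each window of `window_snps` consecutive
#' variants (windows advance by `step_snps` and never span a chromosome
#' boundary), while any pair of retained variants has squared dosage
#' correlation above `r2_max`, the pair with the largest r-squared is found
#' and its lower-priority member removed (the larger discovery p-value under
#' `priority = "p-value"`, ties and `priority = "order"` dropping the later
#' variant). After the pass, no window over the original variant positions
#' contains a retained pair exceeding the threshold. Missing dosages are
#' mean-imputed per variant before correlation.
#'
#' @param panel a [dosage_panel()], variants sorted by chromosome then
#'   position (an error otherwise).
#' @param config a [prune_config()].
#' @param priorities numeric vector aligned with the panel's variants
#'   (discovery p-values); required when `config$priority == "p-value"`.
#' @return character vector of retained variant ids, in panel order.
#' @export
prune_window <- function(panel, config = prune_config(), priorities = NULL) {
  stopifnot(inherits(panel, "dosage_panel"), inherits(config, "prune_config"))
  v <- panel$variants
  ord <- order(match(v$chrom, unique(v$chrom)), v$pos)
  if (!identical(ord, seq_len(nrow(v))))
    stop("panel variants must be sorted by chromosome then position")
  if (config$priority == "p-value") {
    if (is.null(priorities) || length(priorities) != nrow(v))
      stop("priorities (one p-value per panel variant) required for priority = \"p-value\"")
  } else {
    priorities <- seq_len(nrow(v))
  }
  d <- impute_mean(panel$dosages)
  keep <- rep(TRUE, nrow(v))
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    m <- length(idx)
    starts <- if (m <= config$window_snps) 0L
              else seq.int(0L, m - 1L, by = config$step_snps)
    for (s in starts) {
      win <- idx[(s + 1L):min(s + config$window_snps, m)]
      if (length(win) < 2L) next
      repeat {
        act <- win[keep[win]]
        if (length(act) < 2L) break
        r2 <- suppressWarnings(cor(d[, act, drop = FALSE])^2)
        r2[!is.finite(r2)] <- 0
        diag(r2) <- 0
        mx <- max(r2)
        if (mx <= config$r2_max) break
        hit <- which(r2 == mx, arr.ind = TRUE)[1L, ]
        a <- act[hit[1L]]; b <- act[hit[2L]]
        # drop the lower-priority member; ties drop the later variant
        drop <- if (priorities[a] > priorities[b]) a
                else if (priorities[b] > priorities[a]) b
                else max(a, b)
        keep[drop] <- FALSE
      }
    }
  }
  v$variant_id[keep]
}

#' Check the pruning post-condition
#'
#' Scans every window of `window_snps` consecutive original variant
#' positions and verifies that no retained pair exceeds `r2_max`.
#'
#' @param panel the pruned-from [dosage_panel()].
#' @param kept ids returned by [prune_window()].
#' @param config the [prune_config()] used.
#' @return `TRUE` if the post-condition holds, otherwise `FALSE`.
#' @export
prune_check <- function(panel, kept, config) {
  v <- panel$variants
  d <- impute_mean(panel$dosages)
  keep <- v$variant_id %in% kept
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    m <- length(idx)
    for (s in seq.int(0L, max(0L, m - 1L))) {
      win <- idx[(s + 1L):min(s + config$window_snps, m)]
      act <- win[keep[win]]
      if (length(act) < 2L) next
      r2 <- suppressWarnings(cor(d[, act, drop = FALSE])^2)
      r2[!is.finite(r2)] <- 0
      diag(r2) <- 0
      if (max(r2) > config$r2_max) return(FALSE)
    }
  }
  TRUE
}

#' Per-chromosome pruning report
#'
#' @param panel the [dosage_panel()] that was pruned.
#' @param kept retained variant ids.
#' @return data.frame with `chrom`, `before`, `after`.
#' @export
prune_report <- function(panel, kept) {
  v <- panel$variants
  keep <- v$variant_id %in% kept
  agg <- aggregate(cbind(before = rep(1L, nrow(v)), after = as.integer(keep)),
                   by = list(chrom = v$chrom), FUN = sum)
  agg[order(match(agg$chrom, unique(v$chrom))), , drop = FALSE]
}
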