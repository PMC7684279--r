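# Variant QC (duplicates, strand ambiguity, chromosome drop list, imputation
# quality, minor allele frequency, Hardy-Weinberg exact test) and
# discovery/target effect-allele harmonization.

#' QC thresholds
#'
#' @param maf_min minor-allele-frequency floor, in `[0, 0.5)` (default 0.01).
#' @param hwe_alpha Hardy-Weinberg exact-test significance level below which
#'   a variant is excluded (default 1e-6, the conventional GWAS screen).
#' @param info_min minimum imputation quality, in `[0, 1]` (default 0.9).
#' @param drop_ambiguous drop strand-ambiguous (A/T, C/G) SNPs (default TRUE).
#' @param drop_chroms chromosome labels to exclude (default Y and MT).
#' @return an object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(maf_min = 0.01, hwe_alpha = 1e-6, info_min = 0.9,
                          drop_ambiguous = TRUE, drop_chroms = c("Y", "MT")) {
  if (maf_min < 0 || maf_min >= 0.5) stop("maf_min must lie in [0, 0.5)")
  if (hwe_alpha <= 0 || hwe_alpha >= 1) stop("hwe_alpha must lie in (0, 1)")
  if (info_min < 0 || info_min > 1) stop("info_min must lie in [0, 1]")
  structure(list(maf_min = maf_min, hwe_alpha = hwe_alpha, info_min = info_min,
                 drop_ambiguous = isTRUE(drop_ambiguous),
                 drop_chroms = as.character(drop_chroms)),
            class = "qc_thresholds")
}

#' Is an allele pair strand-ambiguous?
#'
#' A SNP is strand-ambiguous when its two alleles are complements of each
#' other (A/T or C/G), so the strand cannot be resolved from the alleles.
#'
#' @param a1,a2 single-base alleles (vectorized).
#' @return logical vector.
#' @export
#' @examples
#' is_strand_ambiguous("A", "T") # TRUE
#' is_strand_ambiguous("A", "G") # FALSE
is_strand_ambiguous <- function(a1, a2) {
  a1 <- toupper(a1); a2 <- toupper(a2)
  ok <- a1 %in% c("A", "C", "G", "T") & a2 %in% c("A", "C", "G", "T")
  if (!all(ok)) stop("non-ACGT allele: ",
                     paste(unique(c(a1, a2)[!c(ok, ok)]), collapse = ", "))
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
  (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

complement_base <- function(a) c(A = "T", C = "G", G = "C", T = "A")[a]

#' Hardy-Weinberg exact test
#'
#' Two-sided exact test of Hardy-Weinberg equilibrium, conditional on the
#' observed allele counts: the p-value sums the probabilities of all
#' heterozygote counts whose conditional probability does not exceed that of
#' the observed count (computed in log space from the hypergeometric-type
#' conditional distribution).
#'
#' @param n_ref_hom,n_het,n_alt_hom non-negative integer genotype counts.
#' @return the exact two-sided p-value.
#' @export
#' @examples
#' hwe_exact_test(100, 0, 0) # monomorphic: p = 1
#' hwe_exact_test(0, 100, 0) # extreme heterozygote excess: p << 1e-6
hwe_exact_test <- function(n_ref_hom, n_het, n_alt_hom) {
  counts <- c(n_ref_hom, n_het, n_alt_hom)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n < 1) stop("total genotype count must be at least 1")
  n_a <- 2 * n_alt_hom + n_het  # the test is symmetric in the two alleles
  hets <- seq.int(n_a %% 2, min(n_a, 2 * n - n_a), by = 2)
  # conditional log-probability of each attainable heterozygote count
  alt_hom <- (n_a - hets) / 2
  ref_hom <- n - alt_hom - hets
  lp <- hets * log(2) + lfactorial(n) -
    lfactorial(ref_hom) - lfactorial(hets) - lfactorial(alt_hom) -
    (lfactorial(2 * n) - lfactorial(n_a) - lfactorial(2 * n - n_a))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[hets == n_het]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Variant quality control
#'
#' Applies, in order: removal of duplicated variant ids, strand-ambiguous
#' alleles, excluded chromosomes (Y and mitochondria by default), low
#' imputation quality (`info >= info_min` retained; variants with missing
#' info are kept), low minor allele frequency (MAF from mean dosage / 2),
#' and Hardy-Weinberg disequilibrium (exact test; applied to hard genotype
#' calls only and skipped for fractional dosages). Each excluded variant is
#' logged once with the first failing rule.
#'
#' @param panel a [dosage_panel()].
#' @param thresholds a [qc_thresholds()].
#' @param hwe_samples optional character vector of sample ids to restrict the
#'   HWE test to (e.g. founders or controls, where equilibrium is expected);
#'   default all samples.
#' @return list with `keep` (character vector of surviving variant ids, in
#'   panel order) and `exclusions` (data.frame `variant_id`, `rule`,
#'   `detail`).
#' @export
variant_qc <- function(panel, thresholds = qc_thresholds(),
                       hwe_samples = NULL) {
  stopifnot(inherits(panel, "dosage_panel"), inherits(thresholds, "qc_thresholds"))
  v <- panel$variants
  m <- nrow(v)
  rule <- rep(NA_character_, m)
  detail <- rep(NA_character_, m)
  mark <- function(i, r, d) {
    sel <- is.na(rule[i])
    rule[i[sel]] <<- r
    detail[i[sel]] <<- rep_len(d, length(i))[sel]
  }
  dup_ids <- unique(v$variant_id[duplicated(v$variant_id)])
  if (length(dup_ids))
    mark(which(v$variant_id %in% dup_ids), "duplicate",
         rep("duplicated variant id", sum(v$variant_id %in% dup_ids)))
  amb <- is_strand_ambiguous(v$ref, v$alt)
  if (thresholds$drop_ambiguous && any(amb))
    mark(which(amb), "ambiguous",
         paste0(v$ref[amb], "/", v$alt[amb]))
  chr_bad <- canon_chrom(v$chrom) %in% thresholds$drop_chroms
  if (any(chr_bad))
    mark(which(chr_bad), "chromosome", v$chrom[chr_bad])
  info_bad <- !is.na(v$info) & v$info < thresholds$info_min
  if (any(info_bad))
    mark(which(info_bad), "info",
         sprintf("info=%.4g < %.4g", v$info[info_bad], thresholds$info_min))
  af <- colMeans(panel$dosages, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  maf_bad <- is.na(maf) | maf < thresholds$maf_min
  if (any(maf_bad))
    mark(which(maf_bad), "maf",
         sprintf("maf=%.4g < %.4g", maf[maf_bad], thresholds$maf_min))
  if (is_hard_calls(panel)) {
    rows <- if (is.null(hwe_samples)) seq_along(panel$samples)
            else {
              r <- match(hwe_samples, panel$samples)
              if (anyNA(r)) stop("hwe_samples not in panel: ",
                                 paste(head(hwe_samples[is.na(r)], 5), collapse = ", "))
              r
            }
    todo <- which(is.na(rule))
    for (j in todo) {
      d <- round(panel$dosages[rows, j])
      d <- d[!is.na(d)]
      p <- hwe_exact_test(sum(d == 0), sum(d == 1), sum(d == 2))
      if (p < thresholds$hwe_alpha) {
        rule[j] <- "hwe"
        detail[j] <- sprintf("hwe_p=%.3g < %.3g", p, thresholds$hwe_alpha)
      }
    }
  }
  keep <- v$variant_id[is.na(rule)]
  if (!length(keep)) warning("no variants survive QC")
  excl <- which(!is.na(rule))
  list(keep = keep,
       exclusions = data.frame(variant_id = v$variant_id[excl],
                               rule = rule[excl], detail = detail[excl],
                               stringsAsFactors = FALSE))
}

#' Harmonize discovery effect alleles with target counted alleles
#'
#' Reconciles each summary-statistic record with the matching target variant
#' (matched by id): if the discovery effect allele equals the target ALT
#' (counted) allele and the other allele equals REF, the weight is kept
#' (`direct`); if effect equals REF and other equals ALT, the weight's sign
#' is flipped (`flipped`); for non-ambiguous SNPs the same two rules are
#' retried after complementing the discovery alleles (`complement-direct`,
#' `complement-flipped`); anything else is `excluded(mismatch)`. Ambiguous
#' (A/T, C/G) pairs are never complement-matched because the two strand
#' readings are indistinguishable.
#'
#' @param sumstats summary-statistics `data.frame` (internal schema).
#' @param variants target variant metadata (`variant_id`, `ref`, `alt`).
#' @return data.frame with `variant_id`, `p_value`, `aligned_weight`
#'   (`NA` for excluded variants) and `match_type`.
#' @export
harmonize_alleles <- function(sumstats, variants) {
  idx <- match(sumstats$variant_id, variants$variant_id)
  keep <- !is.na(idx)
  ss <- sumstats[keep, , drop = FALSE]
  tv <- variants[idx[keep], , drop = FALSE]
  ea <- toupper(ss$effect_allele); oa <- toupper(ss$other_allele)
  ref <- toupper(tv$ref); alt <- toupper(tv$alt)
  amb <- is_strand_ambiguous(ea, oa)
  cea <- complement_base(ea); coa <- complement_base(oa)
  type <- rep("excluded(mismatch)", nrow(ss))
  w <- rep(NA_real_, nrow(ss))
  direct <- ea == alt & oa == ref
  flipped <- ea == ref & oa == alt
  cdirect <- !amb & !direct & !flipped & cea == alt & coa == ref
  cflipped <- !amb & !direct & !flipped & cea == ref & coa == alt
  type[direct] <- "direct"; w[direct] <- ss$weight[direct]
  type[flipped] <- "flipped"; w[flipped] <- -ss$weight[flipped]
  type[cdirect] <- "complement-direct"; w[cdirect] <- ss$weight[cdirect]
  type[cflipped] <- "complement-flipped"; w[cflipped] <- -ss$weight[cflipped]
  data.frame(variant_id = ss$variant_id,
             p_value = ss$p_value,
             aligned_weight = w,
             match_type = type,
             stringsAsFactors = FALSE)
}
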