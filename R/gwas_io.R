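# File I/O: summary statistics, dosage panels (dosage-tsv and VCF dialects),
# phenotype tables, result tables. All delimited formats are tab-separated
# text with a header row; readers validate rather than silently coerce.

canon_chrom <- function(x) {
  x <- sub("^chr", "", as.character(x), ignore.case = TRUE)
  x[x %in% c("M", "mt", "Mt")] <- "MT"
  x
}

# default header synonyms for summary-statistics columns
.ss_synonyms <- list(
  variant_id = c("variant_id", "SNP", "snp", "ID", "id", "rsid", "MarkerName"),
  chromosome = c("chromosome", "CHR", "chr", "chrom"),
  position = c("position", "BP", "bp", "POS", "pos"),
  effect_allele = c("effect_allele", "A1", "a1", "EA", "ALT", "alt"),
  other_allele = c("other_allele", "A2", "a2", "OA", "REF", "ref"),
  weight = c("weight", "BETA", "beta", "b", "effect", "logOR"),
  or_col = c("OR", "or", "odds_ratio"),
  p_value = c("p_value", "P", "p", "pval", "PVAL", "P_VALUE"),
  eaf = c("eaf", "EAF", "FRQ", "freq", "af", "AF"),
  info = c("info", "INFO", "Rsq", "r2_info")
)

resolve_col <- function(nms, keys) {
  hit <- which(nms %in% keys)
  if (length(hit)) hit[1] else NA_integer_
}

#' Read GWAS summary statistics
#'
#' Reads a tab- or whitespace-delimited summary-statistics file with a header
#' row into the validated internal schema. Common header synonyms
#' (SNP/CHR/BP/A1/A2/BETA/OR/P/FRQ/INFO) are recognized automatically; a
#' `column_map` overrides them. If the file carries an odds-ratio column
#' instead of a beta, weights are its natural logarithm (an OR of 1 becomes
#' weight 0).
#'
#' @param path file path.
#' @param column_map optional named character vector mapping internal names
#'   (`variant_id`, `chromosome`, `position`, `effect_allele`, `other_allele`,
#'   `weight` or `or_col`, `p_value`, `eaf`, `info`) to header names.
#' @param strict if `TRUE` (default) rows failing validation abort with their
#'   line numbers; if `FALSE` they are dropped with a warning.
#' @return a `data.frame` with columns `variant_id`, `chromosome`, `position`,
#'   `effect_allele`, `other_allele`, `weight`, `p_value`, `eaf`, `info`
#'   (the last two `NA` when absent).
#' @export
read_summary_stats <- function(path, column_map = NULL, strict = TRUE) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  nms <- names(dt)
  idx <- lapply(.ss_synonyms, resolve_col, nms = nms)
  if (!is.null(column_map)) {
    for (k in names(column_map)) {
      j <- match(column_map[[k]], nms)
      if (is.na(j)) stop("column_map names missing column '", column_map[[k]], "'")
      idx[[k]] <- j
    }
  }
  mandatory <- c("variant_id", "chromosome", "position", "effect_allele",
                 "other_allele", "p_value")
  for (k in mandatory)
    if (is.na(idx[[k]])) stop("mandatory summary-statistics column missing: ", k)
  if (is.na(idx$weight) && is.na(idx$or_col))
    stop("mandatory summary-statistics column missing: weight (BETA or OR)")

  weight <- if (!is.na(idx$weight)) as.numeric(dt[[idx$weight]])
            else log(as.numeric(dt[[idx$or_col]]))
  out <- data.frame(variant_id = as.character(dt[[idx$variant_id]]),
                    chromosome = canon_chrom(dt[[idx$chromosome]]),
                    position = as.integer(dt[[idx$position]]),
                    effect_allele = toupper(as.character(dt[[idx$effect_allele]])),
                    other_allele = toupper(as.character(dt[[idx$other_allele]])),
                    weight = weight,
                    p_value = as.numeric(dt[[idx$p_value]]),
                    eaf = if (!is.na(idx$eaf)) as.numeric(dt[[idx$eaf]]) else NA_real_,
                    info = if (!is.na(idx$info)) as.numeric(dt[[idx$info]]) else NA_real_,
                    stringsAsFactors = FALSE)
  bad <- !is.finite(out$p_value) | out$p_value <= 0 | out$p_value > 1
  bad <- bad | !is.finite(out$weight)
  bad <- bad | is.na(out$position) | out$position < 1
  bad <- bad | out$effect_allele == "" | out$other_allele == "" |
    out$effect_allele == out$other_allele
  if (any(bad)) {
    lines <- which(bad) + 1L  # header is line 1
    msg <- paste0("invalid summary-statistic rows at file lines: ",
                  paste(head(lines, 10), collapse = ", "),
                  if (sum(bad) > 10) sprintf(" (and %d more)", sum(bad) - 10))
    if (strict) stop(msg) else {
      warning(msg, "; rows dropped")
      out <- out[!bad, , drop = FALSE]
    }
  }
  rownames(out) <- NULL
  out
}

#' Write summary statistics
#'
#' @param sumstats a summary-statistics `data.frame` (internal schema).
#' @param path output path (tab-delimited with header).
#' @return invisibly, `path`.
#' @export
write_summary_stats <- function(sumstats, path) {
  keep <- intersect(c("variant_id", "chromosome", "position", "effect_allele",
                      "other_allele", "weight", "p_value", "eaf", "info"),
                    names(sumstats))
  data.table::fwrite(sumstats[, keep, drop = FALSE], path, sep = "\t", na = "NA")
  invisible(path)
}

#' Read a genotype dosage panel
#'
#' Two dialects are supported. `"dosage-tsv"`: tab-delimited, one row per
#' variant, columns `variant_id chrom pos ref alt info` followed by one
#' column per sample holding the ALT-allele dosage in `[0, 2]` (`NA` for
#' missing). `"vcf-dosage"`: a VCF whose genotype FORMAT exposes a `DS`
#' dosage subfield, falling back to hard `GT` genotypes counted as 0/1/2;
#' the counted allele is ALT. Multi-allelic and indel records are skipped
#' with a warning (the pipeline analyzes biallelic SNPs only).
#'
#' @param path file path.
#' @param dialect `"dosage-tsv"` or `"vcf-dosage"`.
#' @return a [dosage_panel()].
#' @export
read_dosages <- function(path, dialect = c("dosage-tsv", "vcf-dosage")) {
  dialect <- match.arg(dialect)
  if (dialect == "dosage-tsv") {
    dt <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE,
                            na.strings = c("NA", "."))
    meta_cols <- c("variant_id", "chrom", "pos", "ref", "alt", "info")
    miss <- setdiff(meta_cols, names(dt))
    if (length(miss)) stop("dosage-tsv lacks columns: ", paste(miss, collapse = ", "))
    samples <- setdiff(names(dt), meta_cols)
    if (!length(samples)) stop("dosage-tsv has no sample columns")
    d <- t(as.matrix(dt[, samples, drop = FALSE]))
    storage.mode(d) <- "double"
    if (any(d < -1e-6 | d > 2 + 1e-6, na.rm = TRUE))
      stop("dosages outside [0, 2] in ", path)
    meta <- dt[, meta_cols, drop = FALSE]
    meta$chrom <- canon_chrom(meta$chrom)
    return(dosage_panel(meta, samples, d))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  alt <- fix$ALT; ref <- fix$REF
  biallelic_snp <- !grepl(",", alt, fixed = TRUE) &
    nchar(ref) == 1L & nchar(alt) == 1L
  if (any(!biallelic_snp))
    warning(sum(!biallelic_snp), " multi-allelic or indel VCF record(s) skipped")
  fmt <- vcf@gt[, 1L]
  has_ds <- all(vapply(strsplit(fmt, ":", fixed = TRUE),
                       function(f) "DS" %in% f, logical(1)))
  if (has_ds) {
    d <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    count_alt <- function(g) {
      ifelse(is.na(g) | g %in% c(".", "./.", ".|."), NA_real_,
             vapply(strsplit(gsub("\\|", "/", g), "/", fixed = FALSE),
                    function(a) sum(a == "1"), numeric(1)))
    }
    d <- apply(gt, 2L, count_alt)
    if (is.null(dim(d))) d <- matrix(d, nrow = nrow(gt),
                                     dimnames = dimnames(gt))
  }
  d <- d[biallelic_snp, , drop = FALSE]
  if (any(d < -1e-6 | d > 2 + 1e-6, na.rm = TRUE))
    stop("VCF dosages outside [0, 2] in ", path)
  fix <- fix[biallelic_snp, , drop = FALSE]
  info_num <- suppressWarnings(
    as.numeric(sub(".*INFO=([0-9.eE+-]+).*", "\\1",
                   ifelse(grepl("INFO=", fix$INFO), fix$INFO, NA))))
  meta <- data.frame(variant_id = fix$ID, chrom = canon_chrom(fix$CHROM),
                     pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
                     info = info_num, stringsAsFactors = FALSE)
  dosage_panel(meta, colnames(d), t(d))
}

#' Write a dosage panel
#'
#' Writes either the dosage-tsv dialect or a minimal VCF with `DS` (dosage)
#' and, for hard calls, `GT` genotype fields; the per-variant imputation
#' quality is carried as `INFO=` in the VCF INFO column.
#'
#' @param panel a [dosage_panel()].
#' @param path output path.
#' @param dialect `"dosage-tsv"` or `"vcf-dosage"`.
#' @return invisibly, `path`.
#' @export
write_dosages <- function(panel, path, dialect = c("dosage-tsv", "vcf-dosage")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(panel, "dosage_panel"))
  if (dialect == "dosage-tsv") {
    out <- cbind(panel$variants[, c("variant_id", "chrom", "pos", "ref", "alt", "info")],
                 as.data.frame(t(panel$dosages)))
    data.table::fwrite(out, path, sep = "\t", na = "NA")
    return(invisible(path))
  }
  v <- panel$variants
  hard <- is_hard_calls(panel)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of ALT allele\">",
               "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation quality\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$samples), collapse = "\t")),
             con)
  fmt <- if (hard) "GT:DS" else "DS"
  gt_of <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(v))) {
    ds <- panel$dosages[, j]
    ds_s <- ifelse(is.na(ds), ".", as.character(signif(ds, 6)))
    cells <- if (hard) {
      g <- ifelse(is.na(ds), "./.", gt_of[round(ds) + 1L])
      paste(g, ds_s, sep = ":")
    } else ds_s
    info_s <- if (is.na(v$info[j])) "." else paste0("INFO=", signif(v$info[j], 6))
    writeLines(paste(c(v$chrom[j], v$pos[j], v$variant_id[j], v$ref[j],
                       v$alt[j], ".", "PASS", info_s, fmt, cells),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a phenotype table
#'
#' Reads and validates the per-individual phenotype table: diagnosis group
#' (`HC`/`FR`/`SCZ`), age, sex (`M`/`F`), education years, ever/never regular
#' smoker, age at daily-smoking initiation, cigarettes per day, current
#' versus former status (smoker-only fields must be missing for
#' never-smokers), and the age at illness onset for cases.
#'
#' @param path tab-delimited file with a header.
#' @return a `data.frame` of class `phenotype_table`.
#' @export
read_phenotypes <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE,
                          na.strings = c("NA", ""))
  validate_phenotypes(dt)
}

#' Validate a phenotype table
#'
#' @param df data.frame in the phenotype schema.
#' @return the validated `phenotype_table` (invisibly usable), with logical
#'   columns coerced.
#' @export
validate_phenotypes <- function(df) {
  needed <- c("sample_id", "group", "age", "sex", "ever_smoker")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stop("phenotype table lacks columns: ", paste(miss, collapse = ", "))
  for (opt in c("education", "age_initiation", "cpd", "current_smoker", "onset_age"))
    if (!opt %in% names(df)) df[[opt]] <- NA
  if (!all(df$group %in% c("HC", "FR", "SCZ")))
    stop("group must be one of HC, FR, SCZ; offending rows: ",
         paste(head(which(!df$group %in% c("HC", "FR", "SCZ"))), collapse = ", "))
  if (!all(df$sex %in% c("M", "F")))
    stop("sex must be M or F")
  df$ever_smoker <- as.logical(df$ever_smoker)
  df$current_smoker <- as.logical(df$current_smoker)
  if (anyNA(df$ever_smoker)) stop("ever_smoker must be present for every row")
  never <- !df$ever_smoker
  filled <- never & (!is.na(df$age_initiation) | !is.na(df$cpd) |
                     !is.na(df$current_smoker))
  if (any(filled))
    stop("smoker-only fields present for never-smokers, rows: ",
         paste(head(which(filled), 10), collapse = ", "))
  noinit <- df$ever_smoker & is.na(df$age_initiation)
  if (any(noinit))
    stop("ever-smokers lacking age_initiation, rows: ",
         paste(head(which(noinit), 10), collapse = ", "))
  if (any(df$age <= 0, na.rm = TRUE)) stop("ages must be positive")
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Write a phenotype table
#'
#' @param pheno a `phenotype_table`.
#' @param path output path (tab-delimited).
#' @return invisibly, `path`.
#' @export
write_phenotypes <- function(pheno, path) {
  data.table::fwrite(as.data.frame(pheno), path, sep = "\t", na = "NA")
  invisible(path)
}

#' Write analysis result tables
#'
#' Writes one tab-delimited file per named table, in deterministic (input)
#' column order, and returns a manifest.
#'
#' @param tables named list of data.frames.
#' @param output_dir directory (created if needed).
#' @return invisibly, a manifest `data.frame` (name, file, rows).
#' @export
write_results <- function(tables, output_dir) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(tables))
  for (i in seq_along(tables)) {
    f <- file.path(output_dir, paste0(names(tables)[i], ".tsv"))
    data.table::fwrite(as.data.frame(tables[[i]]), f, sep = "\t", na = "NA")
    files[i] <- f
  }
  invisible(data.frame(name = names(tables), file = files,
                       rows = vapply(tables, nrow, integer(1)),
                       stringsAsFactors = FALSE))
}
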