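# Association statistics: linear and logistic fits with variance-explained
# measures (adjusted R-squared, Nagelkerke pseudo-R-squared), threshold
# scans, three-group trend, interaction test, and the summary-table
# chi-squared / ANOVA statistics.

assoc_row <- function(threshold, model, fit_sum, n, covariates) {
  data.frame(threshold = threshold,
             model = model,
             coefficient = fit_sum$coefficient,
             se = fit_sum$se,
             p_value = fit_sum$p_value,
             variance_explained = fit_sum$variance_explained,
             incremental_r2 = fit_sum$incremental_r2,
             n = n,
             covariates = if (length(covariates)) paste(covariates, collapse = "+") else "",
             stringsAsFactors = FALSE)
}

check_full_rank <- function(fit) {
  bad <- names(coef(fit))[is.na(coef(fit))]
  if (length(bad))
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
}

build_design <- function(x, covariates) {
  df <- data.frame(.x = as.numeric(x))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(x))
      stop("covariates misaligned with predictor (", nrow(covariates),
           " vs ", length(x), " rows)")
    df <- cbind(df, covariates)
  }
  df
}

#' Linear association of an outcome with a polygenic score
#'
#' Ordinary least squares of `y` on the score plus optional covariates. The
#' variance-explained measure is the full model's adjusted R-squared,
#' `1 - (1 - R2) (n - 1) / (n - p - 1)` with `p` predictors excluding the
#' intercept; `incremental_r2` is the increase of adjusted R-squared over the
#' covariates-only model. The p-value is the two-sided t-test of the score
#' coefficient.
#'
#' @param y numeric outcome.
#' @param x numeric predictor (the PRS).
#' @param covariates optional data.frame of covariates, row-aligned with `y`.
#' @param threshold cutoff label carried into the result (default `NA`).
#' @return a one-row `data.frame` (`threshold`, `model`, `coefficient`, `se`,
#'   `p_value`, `variance_explained`, `incremental_r2`, `n`, `covariates`).
#' @export
fit_linear <- function(y, x, covariates = NULL, threshold = NA_real_) {
  df <- build_design(x, covariates)
  df$.y <- as.numeric(y)
  df <- df[complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  p <- ncol(df) - 1L  # predictors excluding intercept and outcome
  if (n <= p + 1L) stop("too few observations (", n, ") for ", p, " predictors")
  fit <- lm(.y ~ ., data = df)
  check_full_rank(fit)
  sm <- summary(fit)
  adj <- sm$adj.r.squared
  inc <- adj
  if (!is.null(covariates)) {
    fit0 <- lm(.y ~ ., data = df[, c(".y", setdiff(names(df), c(".y", ".x"))), drop = FALSE])
    inc <- adj - summary(fit0)$adj.r.squared
  }
  co <- sm$coefficients[".x", , drop = TRUE]
  assoc_row(threshold, "linear",
            list(coefficient = co[["Estimate"]], se = co[["Std. Error"]],
                 p_value = co[["Pr(>|t|)"]], variance_explained = adj,
                 incremental_r2 = inc),
            n, names(covariates))
}

# Nagelkerke pseudo-R-squared from full and intercept-only log-likelihoods:
# [1 - (L0/L1)^(2/n)] / [1 - L0^(2/n)], computed in log space.
nagelkerke_r2 <- function(ll1, ll0, n) {
  cs <- 1 - exp(2 / n * (ll0 - ll1))
  mx <- 1 - exp(2 / n * ll0)
  if (mx <= 0) return(0)
  max(0, min(1, cs / mx))
}

fit_logistic_glm <- function(formula, data) {
  fit <- withCallingHandlers(
    glm(formula, data = data, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  # a (near-)zero deviance means the classes are perfectly predicted, which a
  # logistic likelihood only reaches in the separation limit
  if (!fit$converged || fit$deviance < 1e-6)
    stop("logistic fit diverged (complete or quasi-complete separation); ",
         "residual deviance = ", format(fit$deviance, digits = 3),
         ", largest |coefficient| = ",
         format(max(abs(coef(fit)), na.rm = TRUE), digits = 3))
  fit
}

#' Logistic association of a binary outcome with a polygenic score
#'
#' Maximum-likelihood logistic regression of `y` on the score plus optional
#' covariates. The variance-explained measure is Nagelkerke's pseudo-R-squared
#' of the full model against the intercept-only model; `incremental_r2` is
#' its increase over the covariates-only model. The p-value is the Wald test
#' of the score coefficient.
#'
#' @inheritParams fit_linear
#' @param y binary outcome (logical or 0/1); both classes must be present.
#' @return a one-row `data.frame`, as [fit_linear()].
#' @export
fit_logistic <- function(y, x, covariates = NULL, threshold = NA_real_) {
  df <- build_design(x, covariates)
  df$.y <- as.numeric(y)
  df <- df[complete.cases(df), , drop = FALSE]
  if (!all(df$.y %in% c(0, 1))) stop("outcome must be binary (0/1 or logical)")
  if (length(unique(df$.y)) < 2L) stop("both outcome classes must be present")
  n <- nrow(df)
  if (sd(df$.x) == 0) {
    # constant score: the model collapses to the covariate-only null
    return(assoc_row(threshold, "logistic",
                     list(coefficient = NA_real_, se = NA_real_,
                          p_value = NA_real_, variance_explained = 0,
                          incremental_r2 = 0),
                     n, names(covariates)))
  }
  fit <- fit_logistic_glm(.y ~ ., df)
  check_full_rank(fit)
  ll1 <- as.numeric(logLik(fit))
  ll_null <- as.numeric(logLik(glm(.y ~ 1, data = df, family = binomial())))
  r2 <- nagelkerke_r2(ll1, ll_null, n)
  inc <- r2
  if (!is.null(covariates)) {
    df0 <- df[, setdiff(names(df), ".x"), drop = FALSE]
    ll0 <- as.numeric(logLik(fit_logistic_glm(.y ~ ., df0)))
    inc <- r2 - nagelkerke_r2(ll0, ll_null, n)
  }
  co <- summary(fit)$coefficients[".x", , drop = TRUE]
  assoc_row(threshold, "logistic",
            list(coefficient = co[["Estimate"]], se = co[["Std. Error"]],
                 p_value = co[["Pr(>|z|)"]], variance_explained = r2,
                 incremental_r2 = inc),
            n, names(covariates))
}

#' Association scan across the threshold grid
#'
#' Fits one model per P_T cutoff of a [prs_profile()] and reports the scan
#' with the best cutoff (maximum variance explained). P-values across
#' cutoffs are deliberately not corrected for multiplicity: the scores at
#' neighbouring cutoffs are strongly correlated, and the scan's selection
#' effect is characterized by simulation instead (see the package vignette).
#'
#' @param profile a [prs_profile()].
#' @param y outcome vector, sample-aligned with the profile (a named vector
#'   is checked against the profile's sample ids). For the three-group
#'   diagnosis scan code HC=0, FR=1, SCZ=2 and use `model = "linear"`.
#' @param model `"linear"` or `"logistic"`.
#' @param covariates optional data.frame, sample-aligned.
#' @return list with `scan` (one row per cutoff; degenerate cutoffs with a
#'   constant score give `NA` rows) and `best` (the row with maximum
#'   variance explained).
#' @export
scan_thresholds <- function(profile, y, model = c("linear", "logistic"),
                            covariates = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(profile, "prs_profile"))
  if (length(y) != length(profile$samples))
    stop("outcome misaligned with profile samples (", length(y), " vs ",
         length(profile$samples), ")")
  if (!is.null(names(y)) && !identical(names(y), profile$samples))
    stop("outcome sample ids do not match the profile")
  fitter <- if (model == "linear") fit_linear else fit_logistic
  rows <- lapply(seq_along(profile$grid), function(i) {
    s <- profile$scores[, i]
    if (sd(s) == 0) {
      r <- assoc_row(profile$grid[i], model,
                     list(coefficient = NA_real_, se = NA_real_,
                          p_value = NA_real_, variance_explained = NA_real_,
                          incremental_r2 = NA_real_),
                     length(y), names(covariates))
      return(r)
    }
    fitter(y, s, covariates, threshold = profile$grid[i])
  })
  scan <- do.call(rbind, rows)
  scan$snp_count <- unname(profile$snp_count)
  if (all(is.na(scan$variance_explained)))
    return(list(scan = scan, best = scan[0, , drop = FALSE]))
  best <- scan[which.max(scan$variance_explained), , drop = FALSE]
  list(scan = scan, best = best)
}

#' Three-group trend of PRS across diagnosis
#'
#' Linear trend fit with diagnosis coded HC=0, FR=1, SCZ=2 as the dependent
#' variable and the PRS as predictor (the equidistant ordinal coding under
#' which an unaffected first-degree relative lies midway between control and
#' case), plus per-group mean and quartile summaries of the score.
#'
#' @param prs numeric score vector.
#' @param groups factor or character with levels `HC`, `FR`, `SCZ` (at least
#'   two present).
#' @param covariates optional data.frame.
#' @return list with `result` (one-row assoc frame) and `group_stats`
#'   (per-group n, mean, q1, median, q3).
#' @export
group_trend <- function(prs, groups, covariates = NULL) {
  groups <- factor(as.character(groups), levels = c("HC", "FR", "SCZ"))
  if (anyNA(groups)) stop("groups must be HC, FR or SCZ")
  if (length(unique(groups)) < 2L) stop("at least two diagnostic groups required")
  code <- as.numeric(groups) - 1
  res <- fit_linear(code, prs, covariates)
  gs <- do.call(rbind, lapply(levels(groups), function(g) {
    x <- prs[groups == g]
    if (!length(x)) return(NULL)
    data.frame(group = g, n = length(x), mean = mean(x),
               q1 = unname(quantile(x, 0.25)), median = median(x),
               q3 = unname(quantile(x, 0.75)), stringsAsFactors = FALSE)
  }))
  list(result = res, group_stats = gs)
}

#' PRS-by-smoking-status interaction on disease risk
#'
#' Logistic model `diagnosis ~ PRS + status + PRS:status` (plus covariates);
#' returns the Wald p-value of the product term.
#'
#' @param prs numeric score vector.
#' @param smoking_status logical (ever = `TRUE`) or factor with two levels.
#' @param diagnosis binary outcome (case = 1).
#' @param covariates optional data.frame.
#' @return list with `p_value`, `coefficient` (interaction term), `n`.
#' @export
interaction_test <- function(prs, smoking_status, diagnosis, covariates = NULL) {
  st <- if (is.logical(smoking_status)) as.numeric(smoking_status)
        else as.numeric(factor(smoking_status)) - 1
  y <- as.numeric(diagnosis)
  if (length(unique(st[!is.na(st)])) < 2L) stop("both smoking statuses must be present")
  if (length(unique(y[!is.na(y)])) < 2L) stop("both outcome classes must be present")
  if (any(table(st, y) == 0)) stop("empty smoking-status by outcome stratum")
  df <- data.frame(.y = y, .x = as.numeric(prs), .st = st)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  df <- df[complete.cases(df), , drop = FALSE]
  rhs <- paste(c(".x * .st", setdiff(names(df), c(".y", ".x", ".st"))), collapse = " + ")
  if (sd(df$.x) == 0) stop("rank-deficient design; collinear column(s): .x, .x:.st")
  fit <- fit_logistic_glm(as.formula(paste(".y ~", rhs)), df)
  check_full_rank(fit)
  co <- summary(fit)$coefficients
  row <- grep("^\\.x:\\.st$", rownames(co))
  list(p_value = co[row, "Pr(>|z|)"],
       coefficient = co[row, "Estimate"],
       n = nrow(df))
}

#' Pearson chi-squared test on a contingency table
#'
#' The classical statistic `sum((O - E)^2 / E)` with expected counts from
#' the margins, `(r - 1)(c - 1)` degrees of freedom and an upper-tail
#' chi-squared p-value (no continuity correction).
#'
#' @param table matrix of non-negative integer counts, at least 2 x 2, with
#'   no zero row or column margin.
#' @return list with `statistic`, `df`, `p_value`, `expected`.
#' @export
#' @examples
#' pearson_chi2(rbind(c(36, 110), c(12, 44), c(33, 97)))
pearson_chi2 <- function(table) {
  tab <- as.matrix(table)
  if (nrow(tab) < 2L || ncol(tab) < 2L) stop("table must be at least 2 x 2")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) stop("zero row or column margin")
  E <- outer(rs, cs) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE), expected = E)
}

#' One-way ANOVA from group summaries
#'
#' Reconstructs the F-test from per-group (n, mean, SD) triples:
#' between-group sum of squares from `n (mean - grand mean)^2`, within-group
#' from `(n - 1) sd^2`.
#'
#' @param n,mean,sd aligned vectors of group sizes (each at least 2), means
#'   and standard deviations (non-negative).
#' @return list with `statistic` (F), `df` (numerator, denominator),
#'   `p_value`.
#' @export
#' @examples
#' anova_from_summaries(c(36, 12, 33), c(20.0, 21.3, 22.6), c(2.2, 2.8, 6.4))
anova_from_summaries <- function(n, mean, sd) {
  if (length(n) < 2L || length(mean) != length(n) || length(sd) != length(n))
    stop("need aligned n, mean, sd for at least two groups")
  if (any(n < 2)) stop("each group needs n >= 2")
  if (any(sd < 0)) stop("standard deviations must be non-negative")
  grand <- sum(n * mean) / sum(n)
  ssb <- sum(n * (mean - grand)^2)
  ssw <- sum((n - 1) * sd^2)
  df1 <- length(n) - 1L
  df2 <- sum(n) - length(n)
  f <- (ssb / df1) / (ssw / df2)
  list(statistic = f, df = c(df1, df2),
       p_value = pf(f, df1, df2, lower.tail = FALSE))
}

#' Late smoking-initiation rates by diagnostic group
#'
#' Among ever-smokers, the per-group proportion initiating daily smoking
#' strictly after `cutoff_age`, with an adjusted group-difference p-value
#' from a logistic regression of the late-initiation indicator on the group
#' trend (HC=0, FR=1, SCZ=2) plus covariates.
#'
#' @param phenotypes a `phenotype_table`.
#' @param cutoff_age age cutoff in years (default 20).
#' @param covariates character subset of phenotype columns to adjust for
#'   (default age and sex).
#' @return list with `rates` (group, ever-smoker n, late n, proportion; `NA`
#'   proportion flags a group without ever-smokers) and `p_value` (`NA` with
#'   a warning when the indicator is degenerate).
#' @export
late_initiation_rates <- function(phenotypes, cutoff_age = 20,
                                  covariates = c("age", "sex")) {
  ph <- as.data.frame(phenotypes)
  ev <- ph[ph$ever_smoker %in% TRUE & !is.na(ph$age_initiation), , drop = FALSE]
  groups <- c("HC", "FR", "SCZ")
  rates <- do.call(rbind, lapply(groups, function(g) {
    x <- ev$age_initiation[ev$group == g]
    data.frame(group = g, n_ever = length(x),
               n_late = sum(x > cutoff_age),
               proportion = if (length(x)) sum(x > cutoff_age) / length(x) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  late <- as.numeric(ev$age_initiation > cutoff_age)
  p <- NA_real_
  if (length(unique(late)) < 2L) {
    warning("late-initiation indicator is degenerate; adjusted test skipped")
  } else {
    df <- data.frame(.y = late,
                     trend = as.numeric(factor(ev$group, levels = groups)) - 1)
    for (cv in covariates) {
      v <- ev[[cv]]
      df[[cv]] <- if (is.character(v) || is.logical(v)) as.numeric(factor(v)) - 1
                  else as.numeric(v)
    }
    df <- df[complete.cases(df), , drop = FALSE]
    fit <- fit_logistic_glm(.y ~ ., df)
    p <- summary(fit)$coefficients["trend", "Pr(>|z|)"]
  }
  list(rates = rates, p_value = p)
}
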