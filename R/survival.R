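# Kaplan-Meier curves and the k-group log-rank test for age at
# daily-smoking initiation (ever-smokers contribute their initiation age as
# an event; never-smokers are censored at their interview age).

#' Kaplan-Meier curves per group
#'
#' Product-limit survival estimate per diagnostic group.
#'
#' @param time positive times (age in years).
#' @param event logical/0-1 event indicator (`FALSE` = censored at `time`).
#' @param group group labels.
#' @return data.frame with `group`, `time`, `n_risk`, `n_event`, `survival`.
#' @export
km_curves <- function(time, event, group) {
  if (any(time <= 0, na.rm = TRUE)) stop("times must be positive")
  group <- factor(group)
  fit <- survival::survfit(survival::Surv(time, as.numeric(event)) ~ group)
  sm <- summary(fit, censored = TRUE)
  strata <- if (is.null(sm$strata)) rep(levels(group)[1], length(sm$time))
            else sub("^group=", "", as.character(sm$strata))
  data.frame(group = strata, time = sm$time, n_risk = sm$n.risk,
             n_event = sm$n.event, survival = sm$surv,
             stringsAsFactors = FALSE)
}

#' Kaplan-Meier curves and k-group log-rank test
#'
#' Compares the survival curves (here: remaining never-smoker fraction by
#' age) across groups with the standard log-rank test: observed versus
#' expected events at each distinct event time under the hypergeometric
#' variance, `k - 1` degrees of freedom. Ties are handled by simultaneous
#' risk-set accounting.
#'
#' @inheritParams km_curves
#' @return list with `curves` (as [km_curves()]), `statistic`, `df`,
#'   `p_value`, and per-group `observed`/`expected` event counts. All-censored
#'   input is an error (the curves are still available via [km_curves()]).
#' @export
km_logrank <- function(time, event, group) {
  group <- factor(group)
  if (nlevels(droplevels(group)) < 2L) stop("at least two groups required")
  curves <- km_curves(time, event, group)
  if (sum(event, na.rm = TRUE) == 0)
    stop("log-rank test undefined: no events observed (see km_curves())")
  sd <- survival::survdiff(survival::Surv(time, as.numeric(event)) ~ group)
  df <- length(sd$n) - 1L
  list(curves = curves,
       statistic = unname(sd$chisq),
       df = df,
       p_value = pchisq(sd$chisq, df, lower.tail = FALSE),
       observed = setNames(as.vector(sd$obs), sub("^group=", "", names(sd$n))),
       expected = setNames(as.vector(sd$exp), sub("^group=", "", names(sd$n))))
}

#' Build survival input from a phenotype table
#'
#' Ever-smokers contribute their age at initiation as an event; never-smokers
#' are censored at their interview age.
#'
#' @param phenotypes a `phenotype_table`.
#' @return data.frame with `time`, `event`, `group`.
#' @export
smoking_survival_input <- function(phenotypes) {
  ph <- as.data.frame(phenotypes)
  time <- ifelse(ph$ever_smoker, ph$age_initiation, ph$age)
  out <- data.frame(time = time, event = ph$ever_smoker, group = ph$group,
                    stringsAsFactors = FALSE)
  out[!is.na(out$time), , drop = FALSE]
}
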