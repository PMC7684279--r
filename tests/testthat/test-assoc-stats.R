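# Regression fits, variance-explained measures, scans, trend/interaction,
# chi-squared and ANOVA-from-summaries.

test_that("linear fit recovers exact relationships and the OLS oracle", {
  x <- 1:10
  res <- suppressWarnings(fit_linear(2 * x + 1, x))  # exact fit warns in summary.lm
  expect_equal(res$variance_explained, 1)
  expect_lt(res$p_value, 1e-12)
  expect_equal(res$coefficient, 2)
  # 8-point dataset against the closed-form normal-equations solution
  set.seed(30)
  x8 <- rnorm(8); z8 <- rnorm(8); y8 <- 1 + 0.5 * x8 - 0.3 * z8 + rnorm(8)
  res8 <- fit_linear(y8, x8, covariates = data.frame(z = z8))
  X <- cbind(1, x8, z8)
  beta_hat <- solve(crossprod(X), crossprod(X, y8))
  expect_equal(res8$coefficient, as.numeric(beta_hat[2, 1]))
  # adjusted R2 formula: 1 - (1 - R2)(n - 1)/(n - p - 1)
  r2_plain <- 1 - sum((y8 - X %*% beta_hat)^2) / sum((y8 - mean(y8))^2)
  expect_equal(res8$variance_explained, 1 - (1 - r2_plain) * 7 / (8 - 2 - 1))
  expect_lt(res8$variance_explained, r2_plain)
})

test_that("linear-fit type-I error is nominal under the null", {
  set.seed(31)
  rej <- mean(replicate(400, fit_linear(rnorm(40), rnorm(40))$p_value < 0.05))
  expect_lt(abs(rej - 0.05), 0.035)  # binomial 99% CI at 400 reps
})

test_that("rank-deficient designs are rejected by name", {
  x <- rnorm(20)
  expect_error(fit_linear(rnorm(20), x, covariates = data.frame(dup = x)),
               "collinear.*dup")
})

test_that("Nagelkerke R2 has the documented anchors", {
  set.seed(32)
  y <- rbinom(40, 1, 0.5)
  # constant predictor collapses to the null model
  df_zero <- fit_logistic(y, rep(0, 40))
  expect_equal(df_zero$variance_explained, 0)
  # saturated binary predictor: coefficient equals the table log odds ratio
  y2 <- rep(c(1, 1, 1, 0, 1, 0, 0, 0), 10)
  x2 <- rep(c(1, 1, 1, 1, 0, 0, 0, 0), 10)
  res <- fit_logistic(y2, x2)
  tab <- table(x2, y2)
  or <- (tab["1", "1"] * tab["0", "0"]) / (tab["1", "0"] * tab["0", "1"])
  expect_equal(res$coefficient, log(or), tolerance = 1e-6)
})

test_that("logistic likelihood matches a brute-force maximization", {
  # 12-observation fixture
  x <- c(-1.5, -1.1, -0.8, -0.4, -0.1, 0.1, 0.3, 0.6, 0.9, 1.2, 1.6, 2.0)
  y <- c(0, 0, 1, 0, 0, 1, 0, 1, 1, 0, 1, 1)
  res <- fit_logistic(y, x)
  nll <- function(b) -sum(y * plogis(b[1] + b[2] * x, log.p = TRUE) +
                          (1 - y) * plogis(-(b[1] + b[2] * x), log.p = TRUE))
  opt <- optim(c(0, 0), nll, method = "BFGS")
  fit <- glm(y ~ x, family = binomial())
  expect_equal(as.numeric(logLik(fit)), -opt$value, tolerance = 1e-6)
  # Nagelkerke from the brute-force likelihoods
  ll0 <- -nll(c(qlogis(mean(y)), 0))
  cs <- 1 - exp(2 / 12 * (ll0 - (-opt$value)))
  expect_equal(res$variance_explained, cs / (1 - exp(2 / 12 * ll0)),
               tolerance = 1e-6)
})

test_that("Nagelkerke R2 is invariant to affine predictor rescaling", {
  set.seed(33)
  x <- rnorm(60)
  y <- rbinom(60, 1, plogis(0.8 * x))
  r1 <- fit_logistic(y, x)$variance_explained
  r2 <- fit_logistic(y, 10 * x - 3)$variance_explained
  expect_equal(r1, r2, tolerance = 1e-8)
})

test_that("separation produces a diverging-fit error", {
  x <- c(rep(-1, 10), rep(1, 10))
  y <- c(rep(0, 10), rep(1, 10))
  expect_error(fit_logistic(y, x), "separation")
})

test_that("threshold scan reduces to a single fit and flags degenerate cutoffs", {
  set.seed(34)
  prof <- structure(list(samples = paste0("i", 1:50),
                         scores = matrix(rnorm(50), 50, 1,
                                         dimnames = list(NULL, "1")),
                         snp_count = c("1" = 10L), grid = 1,
                         standardized = FALSE),
                    class = "prs_profile")
  y <- rnorm(50)
  sc <- scan_thresholds(prof, y, "linear")
  single <- fit_linear(y, prof$scores[, 1], threshold = 1)
  expect_equal(sc$best$coefficient, single$coefficient)
  expect_equal(sc$best$p_value, single$p_value)
  # degenerate all-zero score column yields an NA row, not an error
  prof$scores <- cbind(`0.5` = rep(0, 50), prof$scores)
  prof$grid <- c(0.5, 1)
  prof$snp_count <- c(`0.5` = 0L, `1` = 10L)
  sc2 <- scan_thresholds(prof, y, "linear")
  expect_true(is.na(sc2$scan$p_value[1]))
  expect_equal(sc2$best$threshold, 1)
})

test_that("group trend codes HC/FR/SCZ equidistantly", {
  set.seed(35)
  grp <- rep(c("HC", "FR", "SCZ"), each = 40)
  prs <- rnorm(120) + rep(c(0, 0.5, 1), each = 40)
  gt <- group_trend(prs, grp)
  expect_gt(gt$result$coefficient, 0)
  expect_lt(gt$result$p_value, 0.01)
  expect_equal(gt$group_stats$group, c("HC", "FR", "SCZ"))
  expect_equal(gt$group_stats$n, rep(40L, 3))
  # constant PRS has no trend to fit
  expect_error(group_trend(rep(1, 120), grp), "collinear")
  # dropping FR reduces to the two-group logistic comparison
  keep <- grp != "FR"
  lg <- fit_logistic(as.numeric(grp[keep] == "SCZ"), prs[keep])
  expect_lt(lg$p_value, 0.01)
})

test_that("interaction test is calibrated and null for equal strata effects", {
  # constructed data where the PRS effect is identical in both strata:
  # duplicating a stratum makes the MLE interaction exactly zero
  set.seed(36)
  x <- rnorm(100)
  y <- rbinom(100, 1, plogis(x))
  p_eq <- interaction_test(c(x, x), rep(c(FALSE, TRUE), each = 100),
                           c(y, y))$p_value
  expect_gt(p_eq, 0.99)
  # type-I calibration under an everything-independent null
  rej <- replicate(200, {
    x <- rnorm(120); st <- rbinom(120, 1, 0.5) == 1; y <- rbinom(120, 1, 0.5)
    tryCatch(interaction_test(x, st, y)$p_value < 0.05, error = function(e) NA)
  })
  expect_lt(abs(mean(rej, na.rm = TRUE) - 0.05), 0.045)
  # constant PRS is a rank problem, not a silent zero
  expect_error(interaction_test(rep(1, 40), rep(c(TRUE, FALSE), 20),
                                rbinom(40, 1, 0.5)), "collinear")
})

test_that("Pearson chi-squared matches the textbook oracle", {
  set.seed(37)
  for (i in 1:20) {
    tab <- matrix(rpois(6, 30) + 1, 3, 2)
    got <- pearson_chi2(tab)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$df, unname(ref$parameter))
    expect_equal(got$p_value, unname(ref$p.value))
  }
  # proportional rows are exactly independent
  expect_equal(pearson_chi2(rbind(c(10, 20), c(30, 60)))$statistic, 0)
  expect_error(pearson_chi2(rbind(c(0, 0), c(1, 2))), "margin")
  expect_error(pearson_chi2(matrix(1:3, 3, 1)), "2 x 2")
})

test_that("ANOVA from summaries matches aov on reconstructed data", {
  set.seed(38)
  for (i in 1:10) {
    k <- sample(2:4, 1)
    n <- sample(5:40, k, replace = TRUE)
    mu <- rnorm(k, 20, 3)
    sdv <- runif(k, 0.5, 5)
    got <- anova_from_summaries(n, mu, sdv)
    # rebuild groups with exactly these moments and run stats::aov
    dat <- do.call(rbind, lapply(seq_len(k), function(g) {
      v <- as.vector(scale(seq_len(n[g])))
      data.frame(y = mu[g] + sdv[g] * v, g = factor(g))
    }))
    ref <- anova(aov(y ~ g, data = dat))
    expect_equal(got$statistic, ref$`F value`[1], tolerance = 1e-8)
    expect_equal(got$p_value, ref$`Pr(>F)`[1], tolerance = 1e-8)
  }
  # equal means give F = 0
  expect_equal(anova_from_summaries(c(10, 12), c(5, 5), c(1, 2))$statistic, 0)
  expect_error(anova_from_summaries(c(1, 10), c(1, 2), c(1, 1)), "n >= 2")
  expect_error(anova_from_summaries(c(5, 5), c(1, 2), c(-1, 1)), "non-negative")
})

test_that("late-initiation rates reproduce counts and flag degenerate groups", {
  # a group with 5 of 36 ever-smokers initiating after 20
  ph <- data.frame(
    sample_id = paste0("s", 1:90),
    group = rep(c("HC", "FR", "SCZ"), c(40, 20, 30)),
    age = rep(40, 90), sex = rep(c("M", "F"), 45),
    education = 12,
    ever_smoker = c(rep(TRUE, 36), rep(FALSE, 4),
                    rep(TRUE, 12), rep(FALSE, 8),
                    rep(TRUE, 20), rep(FALSE, 10)),
    age_initiation = NA_real_, cpd = NA_real_, current_smoker = NA,
    onset_age = NA_real_)
  ph$age_initiation[1:36] <- c(rep(25, 5), rep(18, 31))
  ph$age_initiation[41:52] <- c(rep(25, 5), rep(18, 7))
  ph$age_initiation[61:80] <- c(rep(25, 8), rep(18, 12))
  lr <- late_initiation_rates(ph)
  expect_equal(lr$rates$proportion[lr$rates$group == "HC"], 5 / 36)
  expect_equal(round(100 * lr$rates$proportion[lr$rates$group == "HC"], 1), 13.9)
  expect_true(is.finite(lr$p_value))
  # all-early cohort: proportions zero, test degenerate-flagged
  ph2 <- ph
  ph2$age_initiation[!is.na(ph2$age_initiation)] <- 18
  expect_warning(lr2 <- late_initiation_rates(ph2), "degenerate")
  expect_true(all(lr2$rates$proportion == 0))
  expect_true(is.na(lr2$p_value))
})
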