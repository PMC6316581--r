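test_that("odds ratios carry Wald intervals and flip reciprocally", {
  t <- two_by_two(20, 133, 19, 307)
  res <- odds_ratio_wald(t)
  expect_equal(round(res$or, 2), 2.43)
  expect_equal(round(res$ci_low, 2), 1.26)
  expect_equal(round(res$ci_high, 2), 4.70)
  expect_lt(res$p, 0.01)
  # balanced table
  expect_equal(odds_ratio_wald(two_by_two(5, 5, 5, 5))$or, 1)
  # exposure-flip reciprocity
  flip <- odds_ratio_wald(two_by_two(19, 307, 20, 133))
  expect_equal(res$or * flip$or, 1, tolerance = 1e-12)
  # zero cells
  expect_error(odds_ratio_wald(two_by_two(0, 5, 3, 7)), class = "ptc_division")
  hz <- odds_ratio_wald(two_by_two(0, 5, 3, 7), correction = "haldane_if_zero")
  expect_equal(hz$or, (0.5 * 7.5) / (5.5 * 3.5))
})

test_that("logistic regression reduces to the 2x2 odds ratio and closed forms", {
  # single binary predictor
  x <- rep(c(1, 1, 0, 0), c(20, 133, 19, 307))
  y <- rep(c(1, 0, 1, 0), c(20, 133, 19, 307))
  fit <- logistic_fit(matrix(x, ncol = 1, dimnames = list(NULL, "exposed")), y)
  expect_equal(fit$or[fit$term == "exposed"],
               odds_ratio_wald(two_by_two(20, 133, 19, 307))$or,
               tolerance = 1e-8)
  # intercept-only with mean(y) = 0.25
  y0 <- rep(c(1, 0), c(25, 75))
  fit0 <- logistic_fit(matrix(numeric(0), 100, 0), y0)
  expect_equal(fit0$estimate[1], log(1 / 3), tolerance = 1e-8)
})

test_that("logistic regression recovers simulated parameters within 3 SE", {
  set.seed(40)
  n <- 2000
  x <- rnorm(n)
  eta <- -2 + 0.9 * x
  y <- rbinom(n, 1, plogis(eta))
  fit <- logistic_fit(matrix(x, ncol = 1, dimnames = list(NULL, "x")), y)
  expect_lt(abs(fit$estimate[fit$term == "(Intercept)"] - (-2)) /
              fit$se[fit$term == "(Intercept)"], 3)
  expect_lt(abs(fit$estimate[fit$term == "x"] - 0.9) /
              fit$se[fit$term == "x"], 3)
})

test_that("separation and singular designs raise explicit errors", {
  y <- rep(c(0, 1), each = 10)
  x_sep <- as.numeric(y)  # perfect separation
  expect_error(logistic_fit(matrix(x_sep + rnorm(20, sd = 1e-6), ncol = 1,
                                   dimnames = list(NULL, "x")), y),
               class = "ptc_separation")
  X <- cbind(a = rep(1, 20), b = rnorm(20))  # constant column
  expect_error(logistic_fit(X, y), class = "ptc_rank")
})

test_that("contingency tests match independence, hand chi-square, and exact enumeration", {
  # outer-product table: no association
  marg <- outer(c(10, 20), c(6, 9)) / 5
  res <- contingency_test(marg, "chi_square")
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)
  # hand Pearson value for (10,20;20,10)
  res2 <- contingency_test(matrix(c(10, 20, 20, 10), 2), "chi_square")
  expect_equal(res2$statistic, 20 / 3, tolerance = 1e-10)
  # Fisher two-sided vs exhaustive hypergeometric enumeration
  fis <- contingency_test(matrix(c(3, 1, 1, 3), 2), "fisher_2x2")
  expect_equal(round(fis$p, 4), 0.4857)
  expect_equal(fis$p, fisher_enumerate(3, 1, 1, 3), tolerance = 1e-10)
  set.seed(41)
  for (i in 1:20) {
    cells <- rpois(4, 6)
    if (sum(cells) == 0) next
    tab <- matrix(cells, 2)
    expect_equal(contingency_test(tab, "fisher_2x2")$p,
                 fisher_enumerate(cells[1], cells[3], cells[2], cells[4]),
                 tolerance = 1e-8)
  }
})

test_that("Kaplan-Meier matches the product-limit arithmetic", {
  # hand case: times (1,2,3), events (1,1,0) -> S(2) = (2/3)(1/2) = 1/3
  km <- km_estimate(c(1, 2, 3), c(1, 1, 0))
  s2 <- km$curves$surv[km$curves$time == 2]
  expect_equal(s2, 1 / 3, tolerance = 1e-12)
  # no censoring: KM equals the empirical survival function
  tt <- c(2, 4, 4, 7, 9)
  km2 <- km_estimate(tt, rep(1, 5))
  ecdf_surv <- sapply(km2$curves$time, function(u) mean(tt > u))
  expect_equal(km2$curves$surv, ecdf_surv, tolerance = 1e-12)
  # all censored: flat at 1
  km3 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km3$curves$surv == 1))
})

test_that("log-rank test separates shifted groups and ignores labels", {
  set.seed(43)
  t1 <- rexp(50, 1); t2 <- 10 * rexp(50, 1)
  tt <- c(t1, t2); ev <- rep(1, 100)
  g <- rep(c("a", "b"), each = 50)
  res <- logrank_test(tt, ev, g)
  expect_lt(res$p, 0.01)
  expect_equal(res$df, 1)
  relab <- logrank_test(tt, ev, rep(c("b", "a"), each = 50))
  expect_equal(relab$statistic, res$statistic, tolerance = 1e-12)
  # identical groups: statistic ~ 0
  same <- logrank_test(c(t1, t1), rep(1, 100), g)
  expect_lt(same$statistic, 1e-10)
  expect_error(logrank_test(tt, rep(0, 100), g), class = "ptc_validation")
})

test_that("Cox fits match a brute-force partial-likelihood maximization", {
  tt <- c(3, 5, 7, 11, 13, 17)
  ev <- c(1, 1, 0, 1, 1, 0)
  x <- c(1, 0, 1, 0, 1, 0)
  fit <- cox_fit(tt, ev, matrix(x, ncol = 1, dimnames = list(NULL, "x")))
  grid <- seq(-5, 5, by = 1e-4)
  ll <- vapply(grid, cox_partial_loglik, numeric(1), time = tt, event = ev,
               x = x)
  expect_lt(abs(fit$coef - grid[which.max(ll)]), 1e-4)
  # Efron equals Breslow without ties
  fb <- cox_fit(tt, ev, matrix(x, ncol = 1, dimnames = list(NULL, "x")),
                ties = "breslow")
  expect_equal(fit$coef, fb$coef, tolerance = 1e-12)
})

test_that("Cox null and signal recovery stay within 3 SE across replicates", {
  set.seed(44)
  # independent covariate: HR near 1
  n <- 1000
  x <- rbinom(n, 1, 0.5)
  tt <- rexp(n, 0.1); ev <- as.numeric(tt < quantile(tt, 0.8))
  fit <- cox_fit(pmin(tt, quantile(tt, 0.8)), ev,
                 matrix(x, ncol = 1, dimnames = list(NULL, "x")))
  expect_lt(abs(fit$coef) / fit$se, 3)
  # beta recovery across seeded replicates
  fails <- 0
  for (r in 1:20) {
    set.seed(100 + r)
    n <- 150
    xr <- rbinom(n, 1, 0.5)
    tr <- rexp(n, rate = 0.05 * exp(0.7 * xr))
    cr <- runif(n, 0, 40)
    fit_r <- cox_fit(pmin(tr, cr), as.numeric(tr <= cr),
                     matrix(xr, ncol = 1, dimnames = list(NULL, "x")))
    if (abs(fit_r$coef - 0.7) / fit_r$se > 3) fails <- fails + 1
  }
  expect_lte(fails, 1)
})

test_that("the recurrence table pipeline dichotomizes and screens correctly", {
  co <- generate_cohort(synthetic_config(n_genes = 60, n_samples = 500,
                                         seed = 45))
  t2 <- build_table2(co$clinical)
  expect_equal(nrow(t2$univariate), 9)
  expect_setequal(t2$univariate$variable,
                  c("age_55_plus", "male", "aggressive_variant",
                    "extrathyroidal_extension", "pt3_4", "pn1", "braf_like",
                    "high_mutation_burden", "nmf_cluster3"))
  # the aggressive-variant rule counts tall cell variants as exposed
  n_tall <- sum(co$clinical$histologic_variant == "tall cell variant")
  expect_equal(t2$univariate$exposed_total[
    t2$univariate$variable == "aggressive_variant"], n_tall)
  expect_error(build_table2(co$clinical[, -3]), class = "ptc_config")
})

test_that("a null cohort shows no odds ratio beyond 3 SE of 1", {
  cfg <- synthetic_config(n_genes = 60, n_samples = 500,
                          recurrence_rate_by_cluster = rep(0.1, 4), seed = 46)
  co <- generate_cohort(cfg)
  t2 <- build_table2(co$clinical)
  u <- t2$univariate
  # Wald SE recomputed from the reported counts
  se <- sqrt(1 / u$exposed_events + 1 / (u$exposed_total - u$exposed_events) +
               1 / u$unexposed_events +
               1 / (u$unexposed_total - u$unexposed_events))
  expect_true(all(abs(log(u$or)) / se <= 3))
})

test_that("Cox recurrence tables mirror the logistic screening design", {
  co <- generate_cohort(synthetic_config(n_genes = 60, n_samples = 800,
                                         seed = 47))
  t3 <- build_table3(co$clinical)
  expect_equal(nrow(t3$univariate), 9)
  expect_true(all(t3$univariate$hr > 0))
  if (!is.null(t3$multivariate))
    expect_true(all(c("hr", "ci_low", "ci_high") %in% names(t3$multivariate)))
})
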