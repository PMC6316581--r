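#' Two-by-two recurrence table
#'
#' Cell layout: `a` exposed-event, `b` exposed-nonevent, `c` unexposed-event,
#' `d` unexposed-nonevent.
#'
#' @param a,b,c,d non-negative integer counts, total > 0.
#' @return a `TwoByTwoTable` object.
#' @export
two_by_two <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells)) || sum(cells) == 0)
    stop_ptc("ptc_validation", "cells must be non-negative integers with total > 0")
  structure(as.list(cells), class = "TwoByTwoTable")
}

#' Odds ratio with Wald confidence interval
#'
#' `OR = ad / bc`, equal to the exponentiated coefficient of a univariate
#' binomial logistic regression on a binary exposure, with the Wald interval
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` and the corresponding
#' Wald p-value.
#'
#' @param t a [two_by_two()] table.
#' @param alpha two-sided interval level (default 0.05 for 95% CI).
#' @param correction `"none"` (error on zero cells) or `"haldane_if_zero"`
#'   (add 0.5 to every cell only when some cell is zero).
#' @return list with `or`, `ci_low`, `ci_high`, `se_log`, `p`.
#' @export
odds_ratio_wald <- function(t, alpha = 0.05,
                            correction = c("none", "haldane_if_zero")) {
  correction <- match.arg(correction)
  if (!inherits(t, "TwoByTwoTable"))
    stop_ptc("ptc_validation", "t must be a TwoByTwoTable")
  cells <- c(t$a, t$b, t$c, t$d)
  if (any(cells == 0)) {
    if (correction == "none")
      stop_ptc("ptc_division", "zero cell in 2x2 table (use haldane_if_zero)")
    cells <- cells + 0.5
  }
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- qnorm(1 - alpha / 2)
  lo <- exp(log(or) - z * se)
  hi <- exp(log(or) + z * se)
  p <- 2 * pnorm(-abs(log(or) / se))
  list(or = or, ci_low = lo, ci_high = hi, se_log = se, p = p)
}

#' Multivariable binomial logistic regression
#'
#' Maximum likelihood via iteratively reweighted least squares
#' ([stats::glm()]), reporting exponentiated coefficients with Wald intervals.
#' Singular designs and (quasi-)complete separation raise explicit errors.
#'
#' @param X covariate matrix or data frame (no intercept column).
#' @param y binary 0/1 outcomes.
#' @param max_iter IRLS iteration cap (default 25).
#' @param tol IRLS convergence tolerance (default 1e-8).
#' @param alpha CI level (default 0.05).
#' @return data frame with one row per term: `term`, `estimate`, `se`, `z`,
#'   `p`, `or`, `ci_low`, `ci_high`; attributes `converged`, `loglik`, `n`.
#' @export
logistic_fit <- function(X, y, max_iter = 25L, tol = 1e-8, alpha = 0.05) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!all(y %in% c(0, 1)))
    stop_ptc("ptc_validation", "y must be binary 0/1")
  if (nrow(X) != length(y))
    stop_ptc("ptc_validation", "X and y sizes differ")
  if (nrow(X) <= ncol(X) + 1L)
    stop_ptc("ptc_validation", "need more observations than parameters")
  design <- cbind(`(Intercept)` = 1, X)
  if (qr(design)$rank < ncol(design))
    stop_ptc("ptc_rank", "singular design matrix (constant or collinear column)")
  fit <- withCallingHandlers(
    glm.fit(design, y, family = binomial(),
            control = list(maxit = max_iter, epsilon = tol)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        stop_ptc("ptc_separation", "complete or quasi-complete separation detected")
      invokeRestart("muffleWarning")
    })
  beta <- fit$coefficients
  if (any(abs(beta[-1]) > 15))
    stop_ptc("ptc_separation", "diverging coefficient (|beta| > 15): separation")
  # Wald SEs from the IRLS weighted cross-product
  w <- fit$weights
  info <- crossprod(design * sqrt(w))
  se <- sqrt(diag(solve(info)))
  z <- beta / se
  zq <- qnorm(1 - alpha / 2)
  out <- data.frame(term = names(beta), estimate = unname(beta),
                    se = unname(se), z = unname(z),
                    p = unname(2 * pnorm(-abs(z))), or = unname(exp(beta)),
                    ci_low = unname(exp(beta - zq * se)),
                    ci_high = unname(exp(beta + zq * se)),
                    stringsAsFactors = FALSE)
  attr(out, "converged") <- fit$converged
  attr(out, "loglik") <- -fit$deviance / 2
  attr(out, "n") <- length(y)
  if (!fit$converged) warn_ptc("logistic_fit did not converge in %d iterations",
                               max_iter)
  out
}

#' Contingency-table association test
#'
#' Pearson chi-square (no continuity correction) for r x c tables, or the
#' two-sided Fisher exact test (hypergeometric tail summation) for 2 x 2
#' tables. Zero-margin rows/columns are dropped with a warning for the
#' chi-square test.
#'
#' @param tab matrix of non-negative counts.
#' @param method `"chi_square"` or `"fisher_2x2"`.
#' @return list with `method`, `statistic` (chi-square only), `df`, `p`.
#' @export
contingency_test <- function(tab, method = c("chi_square", "fisher_2x2")) {
  method <- match.arg(method)
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop_ptc("ptc_validation", "counts must be non-negative")
  if (method == "fisher_2x2") {
    if (!all(dim(tab) == 2L))
      stop_ptc("ptc_validation", "fisher_2x2 requires a 2x2 table")
    ft <- fisher.test(tab)
    return(list(method = method, statistic = NA_real_, df = NA_integer_,
                p = unname(ft$p.value)))
  }
  keep_r <- rowSums(tab) > 0; keep_c <- colSums(tab) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warn_ptc("dropping %d zero-margin rows/columns",
             sum(!keep_r) + sum(!keep_c))
    tab <- tab[keep_r, keep_c, drop = FALSE]
  }
  if (any(dim(tab) < 2L))
    stop_ptc("ptc_validation", "fewer than 2 informative rows/columns")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(method = method, statistic = unname(ct$statistic),
       df = unname(ct$parameter), p = unname(ct$p.value))
}

#' Kaplan-Meier recurrence-free survival curves
#'
#' Product-limit estimator per group; censored times do not drop the curve.
#'
#' @param time positive follow-up times.
#' @param event binary event indicators (1 = recurrence).
#' @param group optional grouping factor; `NULL` for a single curve.
#' @return list with `curves` (data frame: `group`, `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`) and `median` (named per-group median
#'   survival, `NA` if the curve never crosses 0.5).
#' @export
km_estimate <- function(time, event, group = NULL) {
  if (any(time <= 0)) stop_ptc("ptc_validation", "times must be positive")
  if (!all(event %in% c(0, 1))) stop_ptc("ptc_validation", "event must be 0/1")
  if (is.null(group)) group <- rep("all", length(time))
  group <- factor(group)
  empty <- levels(group)[!levels(group) %in% unique(as.character(group))]
  if (length(empty) > 0) {
    warn_ptc("skipping empty groups: %s", paste(empty, collapse = ", "))
    group <- droplevels(group)
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep(levels(group)[1], length(sm$time)) else
    sub("^group=", "", as.character(sm$strata))
  curves <- data.frame(group = grp, time = sm$time, n_risk = sm$n.risk,
                       n_event = sm$n.event, n_censor = sm$n.censor,
                       surv = sm$surv, stringsAsFactors = FALSE)
  med <- summary(fit)$table
  med <- if (is.matrix(med)) setNames(med[, "median"], sub("^group=", "", rownames(med)))
  else setNames(med[["median"]], levels(group)[1])
  list(curves = curves, median = med)
}

#' Log-rank test between survival curves
#'
#' Observed-minus-expected chi-square over the pooled event times,
#' `df = groups - 1`.
#'
#' @inheritParams km_estimate
#' @param group grouping factor with >= 2 levels.
#' @return list with `statistic`, `df`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  if (sum(event) == 0) stop_ptc("ptc_validation", "no events in any group")
  group <- droplevels(factor(group))
  if (nlevels(group) < 2L) stop_ptc("ptc_validation", "need >= 2 groups")
  sdf <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sdf$n) - 1L
  list(statistic = unname(sdf$chisq), df = df,
       p = pchisq(sdf$chisq, df, lower.tail = FALSE))
}

#' Cox proportional hazards regression
#'
#' Newton-type maximization of the partial likelihood via
#' [survival::coxph()], Efron tie handling by default; exponentiated
#' coefficients with Wald intervals.
#'
#' @inheritParams km_estimate
#' @param X covariate matrix or data frame.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param alpha CI level (default 0.05).
#' @return data frame with `term`, `coef`, `hr`, `se`, `z`, `p`, `ci_low`,
#'   `ci_high`; attributes `loglik` (partial log-likelihood at the optimum)
#'   and `n`.
#' @export
cox_fit <- function(time, event, X, ties = c("efron", "breslow"),
                    alpha = 0.05) {
  ties <- match.arg(ties)
  if (any(time <= 0)) stop_ptc("ptc_validation", "times must be positive")
  if (sum(event) == 0) stop_ptc("ptc_validation", "all observations censored")
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ X, ties = ties),
    warning = function(w) {
      if (grepl("did not converge|infinite", conditionMessage(w)))
        stop_ptc("ptc_convergence", "Cox fit failed: %s", conditionMessage(w))
      suppressWarnings(survival::coxph(survival::Surv(time, event) ~ X,
                                       ties = ties))
    })
  beta <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- beta / se
  zq <- qnorm(1 - alpha / 2)
  terms <- sub("^X", "", names(beta))
  out <- data.frame(term = terms, coef = unname(beta), hr = unname(exp(beta)),
                    se = unname(se), z = unname(z),
                    p = unname(2 * pnorm(-abs(z))),
                    ci_low = unname(exp(beta - zq * se)),
                    ci_high = unname(exp(beta + zq * se)),
                    stringsAsFactors = FALSE)
  attr(out, "loglik") <- fit$loglik[2]
  attr(out, "n") <- fit$n
  out
}

# the nine standard recurrence dichotomies; NA marks samples excluded from a
# given contrast (complete-case)
recurrence_dichotomies <- function(clinical) {
  aggressive <- c("tall cell variant", "columnar variant", "hobnail variant")
  variant <- clinical$histologic_variant
  variant_known <- !is.na(variant) & variant != "normal thyroid"
  driver <- clinical$driver_class
  driver_known <- driver %in% c("RAS-like", "BRAF-like")
  list(
    age_55_plus = clinical$age_years >= 55,
    male = clinical$sex == "Male",
    aggressive_variant = ifelse(variant_known, variant %in% aggressive, NA),
    extrathyroidal_extension = clinical$extrathyroidal_extension == "Present",
    pt3_4 = clinical$pT %in% c("pT3", "pT4"),
    pn1 = clinical$pN == "pN1",
    braf_like = ifelse(driver_known, driver == "BRAF-like", NA),
    high_mutation_burden = clinical$mutation_count > 11,
    nmf_cluster3 = as.character(clinical$cluster) == "NMF3")
}

#' Univariate and multivariate recurrence models
#'
#' Builds the standard recurrence risk-factor table: for each of the nine
#' dichotomized variables (age >= 55, male sex, aggressive histologic variant,
#' extrathyroidal extension, pT3-4, pN1, BRAF-like class, > 11 nonsynonymous
#' mutations, NMF cluster 3 vs rest) a univariate 2x2 odds ratio with Wald CI
#' and p-value is computed against the recurrence status; variables with
#' univariate `p < p_enter` are carried into one multivariable logistic
#' model (complete cases).
#'
#' @param clinical data frame with columns `age_years`, `sex`,
#'   `histologic_variant`, `extrathyroidal_extension`, `pT`, `pN`,
#'   `driver_class`, `mutation_count`, `cluster`, `recurrence`.
#' @param p_enter univariate inclusion threshold (default 0.25).
#' @param alpha CI level (default 0.05).
#' @return list with `univariate` (data frame of counts, OR, CI, p per
#'   variable), `multivariate` ([logistic_fit()] table or NULL), and
#'   `n_multivariate`.
#' @export
build_table2 <- function(clinical, p_enter = 0.25, alpha = 0.05) {
  needed <- c("age_years", "sex", "histologic_variant",
              "extrathyroidal_extension", "pT", "pN", "driver_class",
              "mutation_count", "cluster", "recurrence")
  missing_cols <- setdiff(needed, names(clinical))
  if (length(missing_cols) > 0)
    stop_ptc("ptc_config", "clinical table lacks columns: %s",
             paste(missing_cols, collapse = ", "))
  dich <- recurrence_dichotomies(clinical)
  y <- clinical$recurrence
  rows <- lapply(names(dich), function(v) {
    x <- dich[[v]]
    ok <- !is.na(x) & !is.na(y)
    a <- sum(x[ok] & y[ok] == 1); b <- sum(x[ok] & y[ok] == 0)
    cc <- sum(!x[ok] & y[ok] == 1); d <- sum(!x[ok] & y[ok] == 0)
    orw <- odds_ratio_wald(two_by_two(a, b, cc, d), alpha = alpha,
                           correction = "haldane_if_zero")
    data.frame(variable = v, exposed_events = a, exposed_total = a + b,
               unexposed_events = cc, unexposed_total = cc + d,
               or = orw$or, ci_low = orw$ci_low, ci_high = orw$ci_high,
               p = orw$p, stringsAsFactors = FALSE)
  })
  uni <- do.call(rbind, rows)
  selected <- uni$variable[uni$p < p_enter]
  multi <- NULL; n_multi <- 0L
  if (length(selected) >= 1L) {
    Xsel <- do.call(cbind, lapply(dich[selected], as.numeric))
    colnames(Xsel) <- selected
    ok <- complete.cases(Xsel) & !is.na(y)
    multi <- tryCatch(logistic_fit(Xsel[ok, , drop = FALSE], y[ok],
                                   alpha = alpha),
                      ptcnmf_error = function(e) {
                        warn_ptc("multivariate model failed: %s",
                                 conditionMessage(e))
                        NULL
                      })
    n_multi <- sum(ok)
  }
  list(univariate = uni, multivariate = multi, n_multivariate = n_multi)
}

#' Univariate and multivariate Cox models for recurrence-free survival
#'
#' Same dichotomies as [build_table2()], fitted against `(followup_months,
#' event)` with univariate Cox models; variables with univariate `p < p_enter`
#' enter one multivariable Cox model.
#'
#' @inheritParams build_table2
#' @param ties tie handling passed to [cox_fit()].
#' @return list with `univariate`, `multivariate`, `n_multivariate`.
#' @export
build_table3 <- function(clinical, p_enter = 0.25, ties = "efron",
                         alpha = 0.05) {
  needed <- c("followup_months", "event")
  if (!all(needed %in% names(clinical)))
    stop_ptc("ptc_config", "clinical table lacks followup_months/event")
  dich <- recurrence_dichotomies(clinical)
  tt <- clinical$followup_months; ev <- clinical$event
  rows <- lapply(names(dich), function(v) {
    x <- as.numeric(dich[[v]])
    ok <- !is.na(x) & !is.na(tt) & !is.na(ev)
    fit <- tryCatch(cox_fit(tt[ok], ev[ok],
                            matrix(x[ok], dimnames = list(NULL, v)),
                            ties = ties, alpha = alpha),
                    ptcnmf_error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    data.frame(variable = v, hr = fit$hr, ci_low = fit$ci_low,
               ci_high = fit$ci_high, p = fit$p, stringsAsFactors = FALSE)
  })
  uni <- do.call(rbind, rows)
  selected <- uni$variable[uni$p < p_enter]
  multi <- NULL; n_multi <- 0L
  if (length(selected) >= 1L) {
    Xsel <- do.call(cbind, lapply(dich[selected], as.numeric))
    colnames(Xsel) <- selected
    ok <- complete.cases(Xsel) & !is.na(tt) & !is.na(ev)
    multi <- tryCatch(cox_fit(tt[ok], ev[ok], Xsel[ok, , drop = FALSE],
                              ties = ties, alpha = alpha),
                      ptcnmf_error = function(e) NULL)
    n_multi <- sum(ok)
  }
  list(univariate = uni, multivariate = multi, n_multivariate = n_multi)
}

#' Published TCGA recurrence 2x2 counts
#'
#' The event/total pairs of the published univariate recurrence analysis of
#' the TCGA papillary-thyroid-carcinoma cohort, shipped as a plain-text input
#' table (one row per dichotomized risk factor).
#'
#' @return data frame with `variable`, `exposed_events`, `exposed_total`,
#'   `unexposed_events`, `unexposed_total`.
#' @export
tcga_recurrence_counts <- function() {
  path <- system.file("extdata", "tcga_recurrence_2x2.csv", package = "ptcnmf",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
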