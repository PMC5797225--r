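#' Paired t-test
#'
#' Two-sided paired t-test on the within-pair differences, computed from the
#' textbook statistic `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1` degrees
#' of freedom. Zero-variance differences are flagged degenerate rather than
#' raising: identical vectors give `t = 0, p = 1`; a constant non-zero shift
#' gives an infinite statistic with `p = 0`.
#'
#' @param values_a,values_b equal-length paired numeric vectors, `n >= 2`.
#' @return one-row tibble: `estimate` (mean difference a - b), `statistic`,
#'   `df`, `p_value`, `degenerate`.
#' @export
paired_t <- function(values_a, values_b) {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 2)
  d <- values_a - values_b
  n <- length(d)
  s <- sd(d)
  if (s == 0) {
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(tibble(
      estimate = mean(d), statistic = t_stat, df = n - 1,
      p_value = if (t_stat == 0) 1 else 0, degenerate = TRUE
    ))
  }
  t_stat <- mean(d) / (s / sqrt(n))
  tibble(
    estimate = mean(d), statistic = t_stat, df = n - 1,
    p_value = 2 * pt(-abs(t_stat), n - 1), degenerate = FALSE
  )
}

#' Within-subject ANOVA for the condition effect
#'
#' One-way repeated-measures ANOVA testing the condition effect on a measure,
#' with participant as the blocking factor. Bin-level data are first
#' aggregated to one mean per participant x condition, so with two conditions
#' and `n` participants the test has `(1, n - 1)` degrees of freedom and is
#' algebraically the square of the paired t-test.
#'
#' @param bin_table a per-bin table with `participant`, `condition`, and the
#'   measure column.
#' @param measure column name (string) of the measure to test.
#' @return one-row tibble: `measure`, `F_value`, `df1`, `df2`, `p_value`,
#'   `mean_rested`, `mean_sleep_deprived`.
#' @export
rm_anova_condition <- function(bin_table, measure) {
  agg <- bin_table |>
    group_by(.data$participant, .data$condition) |>
    summarise(value = mean(.data[[measure]], na.rm = TRUE), .groups = "drop")
  if (anyNA(agg$value)) {
    abort(paste0("missing cells for measure '", measure,
                 "'; aggregate or impute first"))
  }
  n_cond <- length(unique(agg$condition))
  counts <- table(agg$participant)
  if (any(counts != n_cond)) {
    abort("each participant needs one aggregated value per condition")
  }
  agg$participant <- factor(agg$participant)
  agg$condition <- factor(agg$condition)
  fit <- aov(value ~ condition + Error(participant), data = agg)
  tab <- summary(fit)[["Error: Within"]][[1]]
  means <- tapply(agg$value, agg$condition, mean)
  tibble(
    measure = measure,
    F_value = tab["condition", "F value"],
    df1 = tab["condition", "Df"],
    df2 = tab["Residuals", "Df"],
    p_value = tab["condition", "Pr(>F)"],
    mean_rested = unname(means[["rested"]]),
    mean_sleep_deprived = unname(means[["sleep_deprived"]])
  )
}

#' Poisson rate model for lane-departure counts
#'
#' Log-linear Poisson regression of event counts with a log-exposure offset
#' (minutes driven per cell), so exponentiated coefficients are rate ratios.
#' Typical uses: condition contrast on session totals, or a per-5-minute-block
#' time trend within a condition.
#'
#' @param data a tibble of counts and covariates.
#' @param formula model formula for the count outcome, e.g.
#'   `count ~ condition` or `count ~ block`.
#' @param exposure column name (string) of the exposure in minutes.
#' @param conf_level Wald confidence level.
#' @return object of class `gaze_rate_model`; `tidy()` gives rate ratios
#'   with CIs.
#' @export
poisson_rate_model <- function(data, formula, exposure = "exposure_min",
                               conf_level = 0.95) {
  stopifnot(exposure %in% names(data), all(data[[exposure]] > 0))
  outcome <- all.vars(formula)[1]
  if (all(data[[outcome]] == 0)) {
    abort("all counts are zero: rate model is not identifiable")
  }
  data$.log_exposure <- log(data[[exposure]])
  fit <- glm(formula, data = data, family = poisson(),
             offset = .log_exposure)
  structure(
    list(fit = fit, conf_level = conf_level, formula = formula),
    class = "gaze_rate_model"
  )
}

wald_exp_tidy <- function(fit, conf_level, label) {
  est <- coef(fit)
  se <- sqrt(diag(vcov_of(fit)))
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- 2 * stats::pnorm(-abs(est / se))
  tibble(
    term = names(est),
    !!label := unname(exp(est)),
    conf_low = unname(exp(est - z * se)),
    conf_high = unname(exp(est + z * se)),
    p_value = unname(p)
  )
}

vcov_of <- function(fit) stats::vcov(fit)

#' @export
tidy.gaze_rate_model <- function(x, ...) {
  wald_exp_tidy(x$fit, x$conf_level, "rate_ratio") |>
    filter(.data$term != "(Intercept)")
}

#' @export
glance.gaze_rate_model <- function(x, ...) {
  tibble(
    null_deviance = x$fit$null.deviance, deviance = x$fit$deviance,
    logLik = as.numeric(logLik(x$fit)), AIC = stats::AIC(x$fit),
    nobs = stats::nobs(x$fit)
  )
}

#' @export
print.gaze_rate_model <- function(x, ...) {
  cat("Poisson rate model:", deparse(x$formula), "\n")
  print(tidy(x))
  invisible(x)
}

#' Polynomial mixed model for a measure's time course
#'
#' Fits, per condition, a linear mixed model of the measure against a raw
#' polynomial in driving time (minutes at bin start) with a per-participant
#' random intercept — nine subjects cannot support random slopes. The
#' polynomial order is selected backward from `max_order`: while the
#' highest-order term's p-value (Satterthwaite) is at or above
#' `alpha`, the term is dropped. A singular fit likewise falls back
#' to the next-lower order with a warning.
#'
#' @param bin_table per-bin table with `participant`, `condition`,
#'   `bin_start_min`, and the measure.
#' @param measure column name (string).
#' @param max_order highest polynomial order tried (default 3).
#' @param alpha retention threshold for the leading term (default 0.05).
#' @return object of class `gaze_poly_fit`: one fit per condition, each with
#'   selected `order`, coefficient table, overall F (joint Satterthwaite test
#'   of all polynomial terms), and `R2` (squared correlation of fitted and
#'   observed values).
#' @export
polynomial_mixed_fit <- function(bin_table, measure, max_order = 3,
                                 alpha = 0.05) {
  fits <- lapply(split(bin_table, bin_table$condition), function(dat) {
    dat <- dat[!is.na(dat[[measure]]), ]
    if (length(unique(dat$bin_start_min)) < 4) {
      abort("need at least 4 distinct time points for polynomial fitting")
    }
    fit_poly_one(dat, measure, max_order, alpha)
  })
  structure(list(fits = fits, measure = measure), class = "gaze_poly_fit")
}

fit_poly_one <- function(dat, measure, max_order, alpha) {
  dat$.y <- dat[[measure]]
  order <- max_order
  fit <- NULL
  repeat {
    if (order < 1) break
    form <- as.formula(paste0(
      ".y ~ poly(bin_start_min, ", order, ", raw = TRUE) + (1 | participant)"
    ))
    fit <- tryCatch(
      withCallingHandlers(
        suppressMessages(lmerTest::lmer(form, data = dat, REML = TRUE)),
        warning = function(w) {
          # raw polynomials put predictors on wildly different scales by
          # construction; the fit itself is checked for singularity below
          if (grepl("different scales|rescal", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        }
      ),
      error = function(e) NULL
    )
    if (is.null(fit) || lme4::isSingular(fit, tol = 1e-5)) {
      warn(paste0("order-", order, " fit singular or failed; trying order ",
                  order - 1))
      order <- order - 1
      next
    }
    ct <- coef(summary(fit))
    lead_p <- ct[nrow(ct), "Pr(>|t|)"]
    if (order > 1 && !is.na(lead_p) && lead_p >= alpha) {
      order <- order - 1
      next
    }
    break
  }
  if (is.null(fit)) abort("no polynomial order could be fitted")
  ct <- coef(summary(fit))
  # joint test of all polynomial terms (overall time effect)
  L <- diag(nrow(ct))[-1, , drop = FALSE]
  ftest <- tryCatch(lmerTest::contest(fit, L, joint = TRUE),
                    error = function(e) NULL)
  fitted_vals <- stats::fitted(fit)
  list(
    order = order,
    coefficients = tibble(
      term = rownames(ct), estimate = ct[, "Estimate"],
      std_error = ct[, "Std. Error"], df = ct[, "df"],
      statistic = ct[, "t value"], p_value = ct[, "Pr(>|t|)"]
    ),
    F_value = if (!is.null(ftest)) ftest[["F value"]] else NA_real_,
    df1 = if (!is.null(ftest)) ftest[["NumDF"]] else NA_real_,
    df2 = if (!is.null(ftest)) ftest[["DenDF"]] else NA_real_,
    p_value = if (!is.null(ftest)) ftest[["Pr(>F)"]] else NA_real_,
    R2 = stats::cor(fitted_vals, dat$.y)^2,
    n = nrow(dat),
    model = fit
  )
}

#' @export
tidy.gaze_poly_fit <- function(x, ...) {
  purrr::imap_dfr(x$fits, function(f, cond) {
    mutate(f$coefficients, condition = cond, order = f$order, .before = 1)
  })
}

#' @export
glance.gaze_poly_fit <- function(x, ...) {
  purrr::imap_dfr(x$fits, function(f, cond) {
    tibble(condition = cond, order = f$order, F_value = f$F_value,
           df1 = f$df1, df2 = f$df2, p_value = f$p_value, R2 = f$R2,
           nobs = f$n)
  })
}

#' @export
print.gaze_poly_fit <- function(x, ...) {
  cat("Polynomial mixed fits for", x$measure, "\n")
  print(glance(x))
  invisible(x)
}

#' Kaplan-Meier curve of driving continuation
#'
#' Product-limit estimate of the probability of still driving, per condition.
#' Early terminations are the events; sessions that reach the cap are
#' censored at it.
#'
#' @param records [session_records()] table.
#' @return object of class `gaze_km`; `tidy()` gives the step function
#'   (`condition`, `time`, `n_risk`, `n_event`, `survival`).
#' @export
km_curve <- function(records) {
  dat <- records
  dat$condition <- factor(dat$condition)
  fit <- survival::survfit(
    survival::Surv(termination_min, early_termination) ~ condition,
    data = dat
  )
  structure(list(fit = fit, records = records), class = "gaze_km")
}

#' @export
tidy.gaze_km <- function(x, ...) {
  s <- summary(x$fit, censored = TRUE)
  strata <- if (is.null(s$strata)) {
    rep(unique(x$records$condition), length(s$time))
  } else {
    sub("^condition=", "", as.character(s$strata))
  }
  tibble(
    condition = strata, time = s$time, n_risk = s$n.risk,
    n_event = s$n.event, survival = s$surv
  )
}

#' @export
print.gaze_km <- function(x, ...) {
  print(x$fit)
  invisible(x)
}

#' Logistic model for per-minute lane-departure occurrence
#'
#' Maximum-likelihood binomial logistic regression of the binary per-minute
#' outcome on a chosen predictor set; exponentiated coefficients are odds
#' ratios with Wald confidence intervals. Entropy predictors are expected on
#' the percent (0-100) scale so odds ratios read "per 1% increase". The
#' common specifications are a single predictor, the base model
#' `condition * driving_min`, and the full model adding the ocular and
#' entropy measures.
#'
#' Quasi-perfect separation (diverging estimates) is detected and flagged in
#' the returned object rather than silently reported.
#'
#' @param minutes per-minute table from [minute_table()].
#' @param predictors character vector of predictor terms (may include
#'   interactions, e.g. `"condition:driving_min"`).
#' @param outcome outcome column (default `"lane_departure"`).
#' @param conf_level Wald confidence level.
#' @return object of class `gaze_logit`: `tidy()` gives odds ratios,
#'   `glance()` fit statistics; `$prob` holds per-row predicted
#'   probabilities.
#' @export
logistic_lane_model <- function(minutes, predictors,
                                outcome = "lane_departure",
                                conf_level = 0.95) {
  form <- as.formula(paste(outcome, "~", paste(predictors, collapse = " + ")))
  dat <- minutes
  if ("condition" %in% names(dat)) {
    dat$condition <- factor(dat$condition,
                            levels = c("rested", "sleep_deprived"))
  }
  fit <- glm(form, data = dat, family = binomial())
  separated <- !fit$converged || any(abs(coef(fit)) > 15)
  if (separated) {
    warn("possible (quasi-)separation: estimates flagged; interpret with care")
  }
  structure(
    list(fit = fit, conf_level = conf_level, formula = form,
         separated = separated,
         prob = as.numeric(predict(fit, type = "response")),
         outcome = fit$model[[outcome]]),
    class = "gaze_logit"
  )
}

#' @export
tidy.gaze_logit <- function(x, ...) {
  wald_exp_tidy(x$fit, x$conf_level, "odds_ratio") |>
    filter(.data$term != "(Intercept)")
}

#' @export
glance.gaze_logit <- function(x, ...) {
  tibble(
    logLik = as.numeric(logLik(x$fit)), AIC = stats::AIC(x$fit),
    deviance = x$fit$deviance, nobs = stats::nobs(x$fit),
    separated = x$separated
  )
}

#' @export
print.gaze_logit <- function(x, ...) {
  cat("Logistic lane-departure model:", deparse(x$formula), "\n")
  print(tidy(x))
  invisible(x)
}

#' Likelihood-ratio test between nested logistic models
#'
#' `2 * (logLik(large) - logLik(small))` referred to a chi-square with
#' degrees of freedom equal to the parameter difference. The models must be
#' fitted on identical rows and the smaller model's terms must nest in the
#' larger's.
#'
#' @param model_small,model_large `gaze_logit` objects.
#' @return one-row tibble: `chi2`, `df`, `p_value`.
#' @export
lr_test <- function(model_small, model_large) {
  small <- model_small$fit; large <- model_large$fit
  if (stats::nobs(small) != stats::nobs(large)) {
    abort("models fitted on different numbers of rows; refit on common rows")
  }
  t_small <- attr(stats::terms(small), "term.labels")
  t_large <- attr(stats::terms(large), "term.labels")
  if (!all(t_small %in% t_large)) {
    abort("models are not nested: small-model terms missing from large model")
  }
  df <- length(coef(large)) - length(coef(small))
  if (df < 0) abort("model_large has fewer parameters than model_small")
  chi2 <- max(0, 2 * (as.numeric(logLik(large)) - as.numeric(logLik(small))))
  tibble(chi2 = chi2, df = df,
         p_value = if (df == 0) 1 else pchisq(chi2, df, lower.tail = FALSE))
}

#' ROC evaluation of predicted probabilities
#'
#' Builds the empirical ROC curve over all thresholds, integrates the AUC by
#' the trapezoidal rule (equivalently the Mann-Whitney two-sample statistic
#' with ties counted 1/2), and reports sensitivity and specificity at the
#' Youden-optimal operating point (maximising sensitivity + specificity - 1).
#'
#' @param predictions numeric risk scores or probabilities.
#' @param outcomes binary outcomes (0/1) aligned with `predictions`.
#' @return object of class `gaze_roc` with `auc`, `sensitivity`,
#'   `specificity`, `threshold` (Youden point), and `curve` (a tibble
#'   `threshold, tpr, fpr`).
#' @export
roc_evaluate <- function(predictions, outcomes) {
  stopifnot(length(predictions) == length(outcomes))
  keep <- !is.na(predictions) & !is.na(outcomes)
  predictions <- predictions[keep]
  outcomes <- as.integer(outcomes[keep])
  if (length(unique(outcomes)) < 2) {
    abort("outcomes contain a single class: AUC undefined")
  }
  r <- pROC::roc(response = outcomes, predictor = predictions,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  best <- pROC::coords(r, x = "best", best.method = "youden",
                       ret = c("threshold", "sensitivity", "specificity"),
                       transpose = FALSE)
  best <- best[1, , drop = FALSE]  # ties: first Youden-optimal point
  curve <- tibble(
    threshold = r$thresholds,
    tpr = r$sensitivities,
    fpr = 1 - r$specificities
  )
  structure(
    list(auc = as.numeric(pROC::auc(r)),
         sensitivity = best$sensitivity, specificity = best$specificity,
         threshold = best$threshold, curve = curve),
    class = "gaze_roc"
  )
}

#' @export
tidy.gaze_roc <- function(x, ...) x$curve

#' @export
glance.gaze_roc <- function(x, ...) {
  tibble(auc = x$auc, sensitivity = x$sensitivity,
         specificity = x$specificity, threshold = x$threshold)
}

#' @export
print.gaze_roc <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC = %.3f; Youden point: sens = %.3f, spec = %.3f at %.4g\n",
    x$auc, x$sensitivity, x$specificity, x$threshold
  ))
  invisible(x)
}

#' Write ROC curve points to CSV (`threshold,tpr,fpr`)
#'
#' @param roc a `gaze_roc` object.
#' @param path file path.
#' @export
write_roc_csv <- function(roc, path) {
  readr::write_csv(roc$curve, path)
  invisible(path)
}
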