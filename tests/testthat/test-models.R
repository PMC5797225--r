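test_that("paired t handles degenerate and textbook cases", {
  x <- c(1, 2, 3, 4)
  same <- paired_t(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)

  withr::local_seed(41)
  a <- rnorm(9) + 1
  b <- a - 1 + rnorm(9, 0, 1e-3)  # differences ~ +1 with tiny jitter
  up <- paired_t(a, b)
  expect_gt(up$statistic, 100)
  expect_lt(up$p_value, 1e-6)

  # oracle: stats::t.test on random paired normals
  for (i in 1:10) {
    u <- rnorm(9); v <- rnorm(9)
    ours <- paired_t(u, v)
    ref <- t.test(u, v, paired = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("within-subject ANOVA equals the squared paired t on two conditions", {
  withr::local_seed(42)
  for (i in 1:5) {
    base <- rnorm(9, 50, 10)
    dat <- tibble::tibble(
      participant = rep(sprintf("P%02d", 1:9), 2),
      condition = rep(c("rested", "sleep_deprived"), each = 9),
      value = c(base + rnorm(9), base + 2 + rnorm(9))
    )
    a <- rm_anova_condition(dat, "value")
    t2 <- paired_t(dat$value[dat$condition == "rested"],
                   dat$value[dat$condition == "sleep_deprived"])
    expect_equal(a$F_value, t2$statistic^2, tolerance = 1e-8)
    expect_equal(a$df1, 1)
    expect_equal(a$df2, 8)
    expect_equal(a$p_value, t2$p_value, tolerance = 1e-8)
  }
})

test_that("ANOVA F collapses to 0 when the mean condition difference is zero", {
  # paired differences sum to zero exactly, so the condition SS vanishes
  d <- c(-4, -3, -2, -1, 0, 1, 2, 3, 4) / 10
  dat <- tibble::tibble(
    participant = rep(sprintf("P%02d", 1:9), 2),
    condition = rep(c("rested", "sleep_deprived"), each = 9),
    value = c(10 + seq_len(9), 10 + seq_len(9) + d)
  )
  a <- rm_anova_condition(dat, "value")
  expect_lt(a$F_value, 1e-10)
})

test_that("Poisson rate model recovers a known rate ratio and a null trend", {
  withr::local_seed(43)
  n <- 30000
  dat <- tibble::tibble(
    condition = rep(c("rested", "sleep_deprived"), each = n),
    exposure_min = 1,
    count = c(rpois(n, 0.2), rpois(n, 0.4))
  )
  fit <- poisson_rate_model(dat, count ~ condition)
  rr <- tidy(fit)
  expect_equal(rr$rate_ratio, 2.0, tolerance = 0.05)
  expect_true(rr$conf_low < 2 & rr$conf_high > 2)

  null_dat <- tibble::tibble(block = rep(1:24, each = 500), exposure_min = 5,
                             count = rpois(12000, 1.0))
  null_rr <- tidy(poisson_rate_model(null_dat, count ~ block))
  expect_true(null_rr$conf_low < 1 & null_rr$conf_high > 1)

  allz <- tibble::tibble(condition = c("rested", "sleep_deprived"),
                         exposure_min = 10, count = 0L)
  expect_error(poisson_rate_model(allz, count ~ condition),
               "not identifiable")
})

test_that("exposure offsets put rate ratios on the per-minute scale", {
  withr::local_seed(44)
  dat <- tibble::tibble(
    condition = rep(c("rested", "sleep_deprived"), each = 2000),
    exposure_min = rep(c(10, 2), 2000),
    rate = ifelse(condition == "sleep_deprived", 0.3, 0.1)
  ) |>
    dplyr::mutate(count = rpois(dplyr::n(), rate * exposure_min))
  rr <- tidy(poisson_rate_model(dat, count ~ condition))
  expect_equal(rr$rate_ratio, 3.0, tolerance = 0.1)
})

test_that("polynomial order selection recovers the generating order", {
  withr::local_seed(45)
  times <- (0:23) * 5
  mk <- function(f, sd, ri = 2) {
    tidyr::crossing(participant = sprintf("P%02d", 1:9),
                    bin_start_min = times) |>
      dplyr::mutate(
        condition = "rested",
        value = f(bin_start_min) +
          rep(rnorm(9, 0, ri), each = length(times)) + rnorm(dplyr::n(), 0, sd)
      )
  }
  lin <- polynomial_mixed_fit(mk(function(x) 10 + 0.5 * x, 3), "value")
  expect_equal(lin$fits$rested$order, 1)

  # cubic blink-rate time course (coefficients in 5-minute block units)
  cub_f <- function(x) 30.727 + 1.964 * (x / 5) - 0.033 * (x / 5)^2 +
    0.0002 * (x / 5)^3
  cub <- polynomial_mixed_fit(mk(cub_f, 0.3, ri = 1), "value")
  f <- cub$fits$rested
  expect_equal(f$order, 3)
  truth <- c(30.727, 1.964 / 5, -0.033 / 25, 0.0002 / 125)
  expect_true(all(abs(f$coefficients$estimate - truth) <=
                    2 * f$coefficients$std_error))
  expect_gt(f$R2, 0.9)

  flat <- polynomial_mixed_fit(mk(function(x) rep(20, length(x)), 2), "value")
  cf <- flat$fits$rested$coefficients
  expect_true(all(cf$p_value[-1] > 0.05))
})

test_that("Kaplan-Meier estimates match hand-computed product limits", {
  none <- session_records(sprintf("P%d", 1:5), "rested", rep(120, 5))
  k0 <- tidy(km_curve(none))
  expect_true(all(k0$survival == 1))
  expect_true(all(k0$n_event == 0))

  # six of nine terminate early, all before any censoring
  six <- session_records(
    sprintf("P%d", 1:9), "sleep_deprived",
    c(30, 40, 50, 60, 70, 80, 120, 120, 120)
  )
  k6 <- tidy(km_curve(six))
  expect_equal(min(k6$survival), 1 - 6 / 9, tolerance = 1e-12)

  one <- session_records("P1", "sleep_deprived", 45)
  k1 <- tidy(km_curve(one))
  expect_equal(k1$survival[k1$time == 45], 0)

  # 5 subjects, censoring interleaved: event at 30 (5 at risk), event + a
  # censoring at 50 (4 at risk), event at 80 (2 at risk):
  # S = 4/5, then 4/5 * 3/4 = 0.6, then 0.6 * 1/2 = 0.3
  five <- session_records(
    sprintf("P%d", 1:5), "sleep_deprived", c(30, 50, 50, 80, 120)
  )
  five$early_termination <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  k5 <- tidy(km_curve(five))
  expect_equal(k5$survival[k5$time == 30], 0.8, tolerance = 1e-12)
  expect_equal(k5$survival[k5$time == 50], 0.6, tolerance = 1e-12)
  expect_equal(k5$survival[k5$time == 80], 0.3, tolerance = 1e-12)
})

test_that("logistic model: null predictor CI covers 1, recovery within 2 SE", {
  withr::local_seed(46)
  n <- 6000
  noise <- tibble::tibble(
    lane_departure = rbinom(n, 1, 0.3),
    driving_min = runif(n, 0, 120)
  )
  m0 <- logistic_lane_model(noise, "driving_min")
  td <- tidy(m0)
  expect_true(td$conf_low < 1 & td$conf_high > 1)

  sim <- simulate_lane_minutes(n_participants = 40, seed = 99)
  m <- logistic_lane_model(sim, c("condition", "driving_min", "Hs_pct"))
  est <- coef(m$fit)
  se <- sqrt(diag(vcov(m$fit)))
  expect_lt(abs(est[["conditionsleep_deprived"]] - log(3.20)),
            2 * se[["conditionsleep_deprived"]])
  expect_lt(abs(est[["driving_min"]] - log(1.014)), 2 * se[["driving_min"]])
  expect_lt(abs(est[["Hs_pct"]] - log(1.07)), 2 * se[["Hs_pct"]])
})

test_that("doubling the generative log-odds doubles the fitted log-OR", {
  withr::local_seed(47)
  mk <- function(beta) {
    x <- rnorm(20000)
    tibble::tibble(x = x, lane_departure = rbinom(20000, 1, plogis(-1 + beta * x)))
  }
  b1 <- coef(logistic_lane_model(mk(0.4), "x")$fit)[["x"]]
  b2 <- coef(logistic_lane_model(mk(0.8), "x")$fit)[["x"]]
  expect_equal(b2 / b1, 2, tolerance = 0.15)
})

test_that("separation is flagged", {
  sep <- tibble::tibble(x = c(rep(0, 20), rep(1, 20)),
                        lane_departure = c(rep(0L, 20), rep(1L, 20)))
  expect_warning(m <- logistic_lane_model(sep, "x"), "separation")
  expect_true(m$separated)
})

test_that("likelihood-ratio test behaves at the null and under signal", {
  withr::local_seed(48)
  sim <- simulate_lane_minutes(n_participants = 20, seed = 7)
  m1 <- logistic_lane_model(sim, "driving_min")
  expect_equal(lr_test(m1, m1)$chi2, 0)
  expect_equal(lr_test(m1, m1)$p_value, 1)

  # adding a pure-noise predictor: chi2 ~ chi-square(1)
  chis <- replicate(120, {
    n <- 400
    dat <- tibble::tibble(lane_departure = rbinom(n, 1, 0.3),
                          z = rnorm(n), w = rnorm(n))
    small <- logistic_lane_model(dat, "z")
    large <- logistic_lane_model(dat, c("z", "w"))
    lr_test(small, large)$chi2
  })
  expect_equal(mean(chis), 1, tolerance = 0.35)
  ks <- suppressWarnings(stats::ks.test(chis, stats::pchisq, df = 1))
  expect_gt(ks$p.value, 0.01)

  m2 <- logistic_lane_model(sim, c("driving_min", "condition", "Hs_pct"))
  expect_lt(lr_test(m1, m2)$p_value, 0.001)

  m_other <- logistic_lane_model(sim[-1, ], "driving_min")
  expect_error(lr_test(m_other, m2), "different numbers of rows")
  expect_error(lr_test(logistic_lane_model(sim, "minute"), m2), "not nested")
})

test_that("ROC: perfect, chance-level, and the Mann-Whitney identity", {
  out <- c(rep(0, 50), rep(1, 50))
  perfect <- roc_evaluate(out, out)
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)

  withr::local_seed(49)
  big <- roc_evaluate(runif(4000), rbinom(4000, 1, 0.5))
  expect_lt(abs(big$auc - 0.5), 0.05)

  # AUC == U / (n1 n2), ties counted 1/2, on small fixtures
  for (i in 1:25) {
    pred <- sample(1:5, 8, replace = TRUE)  # ties likely
    outc <- c(rep(0, 4), rep(1, 4))
    pos <- pred[outc == 1]; neg <- pred[outc == 0]
    u <- 0
    for (a in pos) for (b in neg) u <- u + (a > b) + 0.5 * (a == b)
    expect_equal(roc_evaluate(pred, outc)$auc, u / 16, tolerance = 1e-12)
  }

  expect_error(roc_evaluate(runif(5), rep(1, 5)), "single class")
})

test_that("logistic OR and Poisson RR Wald intervals attain nominal coverage", {
  withr::local_seed(50)
  reps <- 120
  cover_or <- logical(reps)
  cover_rr <- logical(reps)
  for (i in 1:reps) {
    n <- 800
    x <- rep(0:1, each = n / 2)
    yl <- rbinom(n, 1, plogis(-1 + log(2) * x))
    tl <- tidy(logistic_lane_model(
      tibble::tibble(lane_departure = yl, x = x), "x"
    ))
    cover_or[i] <- tl$conf_low <= 2 && 2 <= tl$conf_high
    yp <- rpois(n, exp(log(0.3) + log(3) * x))
    tp <- tidy(poisson_rate_model(
      tibble::tibble(count = yp, x = x, exposure_min = 1), count ~ x
    ))
    cover_rr[i] <- tp$conf_low <= 3 && 3 <= tp$conf_high
  }
  expect_gte(mean(cover_or), 0.88)
  expect_gte(mean(cover_rr), 0.88)
})
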