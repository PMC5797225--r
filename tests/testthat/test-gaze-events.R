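test_that("I-DT detects a zero-dispersion run as one fixation", {
  smp <- const_samples(10, 100, 100)
  fx <- detect_fixations(smp)
  expect_equal(nrow(fx), 1)
  expect_equal(fx$duration_ms, 180)
  expect_equal(fx$cx_px, 100)
  expect_equal(fx$cy_px, 100)
})

test_that("I-DT enforces the minimum-duration threshold", {
  smp <- gaze_samples(c(0, 20, 40), rep(0, 3), rep(0, 3))
  expect_equal(nrow(detect_fixations(smp)), 0)
})

test_that("I-DT enforces the dispersion threshold", {
  n <- 20
  smp <- gaze_samples(seq(0, by = 20, length.out = n),
                      rep(0, n), rep(c(0, 200), n / 2))
  expect_equal(nrow(detect_fixations(smp)), 0)
})

test_that("I-DT output is non-overlapping and satisfies both thresholds", {
  withr::local_seed(11)
  for (rep in 1:20) {
    n <- 400
    # piecewise-stationary positions with jumps, plus dropouts
    centers <- cbind(runif(8, 0, 1200), runif(8, 0, 900))
    seg <- sort(sample(1:8, n, replace = TRUE))
    smp <- gaze_samples(
      seq(0, by = 20, length.out = n),
      centers[seg, 1] + rnorm(n, 0, 15),
      centers[seg, 2] + rnorm(n, 0, 15),
      valid = runif(n) > 0.05
    )
    fx <- detect_fixations(smp, 80, 100)
    if (nrow(fx) > 1) {
      expect_true(all(fx$onset_ms[-1] >= fx$offset_ms[-nrow(fx)]))
    }
    for (i in seq_len(nrow(fx))) {
      inside <- smp$t_ms >= fx$onset_ms[i] & smp$t_ms <= fx$offset_ms[i]
      expect_true(all(smp$valid[inside]))
      disp <- diff(range(smp$x_px[inside])) + diff(range(smp$y_px[inside]))
      expect_lte(disp, 100)
      expect_gte(fx$offset_ms[i] - fx$onset_ms[i], 80)
    }
  }
})

test_that("fixation count is invariant under uniform time translation", {
  withr::local_seed(12)
  n <- 500
  x <- cumsum(rnorm(n, 0, 8)) + 400
  y <- cumsum(rnorm(n, 0, 8)) + 400
  smp <- gaze_samples(seq(0, by = 20, length.out = n), x, y)
  shifted <- smp
  shifted$t_ms <- shifted$t_ms + 123456
  expect_equal(nrow(detect_fixations(smp)), nrow(detect_fixations(shifted)))
})

test_that("unsorted timestamps signal a malformed session", {
  smp <- tibble::tibble(t_ms = c(0, 40, 20), x_px = 0, y_px = 0, valid = TRUE)
  expect_error(detect_fixations(smp), "strictly increasing")
})

test_that("blink detection finds maximal invalid runs", {
  smp <- const_samples(20, 0, 0)
  smp$valid[6:10] <- FALSE
  bl <- detect_blinks(smp)
  expect_equal(nrow(bl), 1)
  expect_equal(bl$duration_ms, 100)  # 5 samples at 20 ms spacing

  expect_equal(nrow(detect_blinks(const_samples(20, 0, 0))), 0)

  smp$valid[15:16] <- FALSE
  expect_equal(nrow(detect_blinks(smp)), 2)
})

test_that("blink filter is boundary-inclusive, order-preserving, idempotent", {
  bl <- tibble::tibble(onset_ms = c(0, 1000, 2000),
                       offset_ms = c(120, 1280, 2350),
                       duration_ms = c(120, 280, 350))
  kept <- filter_blinks(bl)
  expect_equal(kept$duration_ms, c(120, 280))
  expect_equal(attr(kept, "microsleeps")$duration_ms, 350)

  at_bound <- filter_blinks(tibble::tibble(onset_ms = 0, offset_ms = 300,
                                           duration_ms = 300))
  expect_equal(nrow(at_bound), 1)

  expect_equal(nrow(filter_blinks(bl[0, ])), 0)

  twice <- filter_blinks(kept)
  expect_equal(twice$duration_ms, kept$duration_ms)
})

test_that("saccade amplitudes scale centroid distances", {
  fx <- tibble::tibble(onset_ms = c(0, 500, 1000), offset_ms = c(400, 900, 1400),
                       duration_ms = 400,
                       cx_px = c(0, 0, 300), cy_px = c(0, 100, 400))
  sc <- saccade_amplitudes(fx, deg_per_px = 0.05)
  expect_equal(sc$amplitude_deg[1], 5.0)
  expect_equal(sc$amplitude_deg[2], sqrt(300^2 + 300^2) * 0.05)

  # 3-4-5 triangle
  fx2 <- fx[c(1, 3), ]
  expect_equal(saccade_amplitudes(fx2, 0.05)$amplitude_deg, 25.0)

  same <- tibble::tibble(onset_ms = c(0, 500), offset_ms = c(400, 900),
                         duration_ms = 400, cx_px = c(10, 10), cy_px = c(5, 5))
  expect_equal(saccade_amplitudes(same)$amplitude_deg, 0)

  expect_equal(nrow(saccade_amplitudes(fx[1, ])), 0)
})

test_that("ocular summaries use onset-based bin assignment and per-minute rates", {
  fx <- tibble::tibble(onset_ms = seq(0, 59000, by = 1000),
                       offset_ms = seq(500, 59500, by = 1000),
                       duration_ms = 500, cx_px = 0, cy_px = 0)
  empty_sc <- tibble::tibble(onset_ms = numeric(), offset_ms = numeric(),
                             amplitude_deg = numeric())
  empty_bl <- tibble::tibble(onset_ms = numeric(), offset_ms = numeric(),
                             duration_ms = numeric())
  s <- summarize_ocular(fx, empty_sc, empty_bl, 0, 60000)
  expect_equal(s$fixation_rate, 60)
  expect_equal(s$blink_rate, 0)
  expect_true(is.na(s$blink_duration_ms))

  bl <- tibble::tibble(onset_ms = seq(0, 29000, by = 1000)[1:30],
                       offset_ms = seq(200, 29200, by = 1000)[1:30],
                       duration_ms = 200)
  s2 <- summarize_ocular(fx[0, ], empty_sc, bl, 0, 30000)
  expect_equal(s2$blink_rate, 60)
  expect_equal(s2$blink_duration_ms, 200)

  expect_error(summarize_ocular(fx, fx[0, ], bl, 1000, 1000), "bin")
})

test_that("per-bin fixation counts over a partition conserve the total", {
  withr::local_seed(13)
  fx <- tibble::tibble(
    onset_ms = sort(runif(300, 0, 600000)),
    offset_ms = NA_real_, duration_ms = 400, cx_px = 0, cy_px = 0
  )
  fx$offset_ms <- fx$onset_ms + 400
  empty_sc <- tibble::tibble(onset_ms = numeric(), offset_ms = numeric(),
                             amplitude_deg = numeric())
  empty_bl <- tibble::tibble(onset_ms = numeric(), offset_ms = numeric(),
                             duration_ms = numeric())
  counts <- vapply(0:9, function(b) {
    summarize_ocular(fx, empty_sc, empty_bl, b * 60000,
                     (b + 1) * 60000)$n_fixations
  }, integer(1))
  expect_equal(sum(counts), 300)
})

test_that("gaze and event CSV dialects round-trip", {
  withr::local_seed(14)
  dir <- withr::local_tempdir()
  smp <- gaze_samples(seq(0, 980, 20), runif(50, 0, 1280), runif(50, 0, 960),
                      valid = runif(50) > 0.1)
  pth <- file.path(dir, "gaze.csv")
  write_gaze_csv(smp, pth)
  back <- read_gaze_csv(pth)
  expect_equal(as.data.frame(back), as.data.frame(smp), tolerance = 1e-12)

  fx <- detect_fixations(smp)
  bl <- detect_blinks(smp)
  sc <- saccade_amplitudes(fx)
  ev_path <- file.path(dir, "events.csv")
  write_events_csv(fx, sc, bl, ev_path)
  ev <- read_events_csv(ev_path)
  expect_equal(nrow(ev$fixations), nrow(fx))
  expect_equal(ev$saccades$amplitude_deg, sc$amplitude_deg, tolerance = 1e-9)
  expect_equal(ev$blinks$duration_ms, bl$duration_ms)
})
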