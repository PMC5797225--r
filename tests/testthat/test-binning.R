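# small hand-built study tables: 2 participants x 2 conditions, 5-min bins,
# one early termination at 80 min
mk_small_study <- function() {
  records <- session_records(
    participant = c("P01", "P01", "P02", "P02"),
    condition = c("rested", "sleep_deprived", "rested", "sleep_deprived"),
    termination_min = c(120, 120, 120, 80)
  )
  keys <- records |>
    dplyr::mutate(n_bins = ceiling(termination_min / 5))
  ocular <- purrr::pmap_dfr(keys, function(participant, condition,
                                           termination_min,
                                           early_termination, n_bins) {
    tibble::tibble(
      participant = participant, condition = condition,
      bin_index = seq_len(n_bins),
      blink_rate = 40 + bin_index, blink_duration_ms = 180,
      fixation_rate = 75 - bin_index, fixation_duration_ms = 550,
      saccade_amplitude_deg = 20
    )
  })
  entropy <- purrr::pmap_dfr(keys, function(participant, condition,
                                            termination_min,
                                            early_termination, n_bins) {
    tibble::tibble(
      participant = participant, condition = condition,
      bin_index = seq_len(n_bins),
      Hs_norm = 0.2 + 0.005 * bin_index, Hs_pct = 100 * Hs_norm,
      Ht_norm = 0.7, Ht_pct = 70
    )
  })
  lane <- purrr::pmap_dfr(keys, function(participant, condition,
                                         termination_min,
                                         early_termination, n_bins) {
    tibble::tibble(
      participant = participant, condition = condition,
      minute = seq_len(termination_min),
      count = rep(c(0L, 1L, 0L, 0L, 2L), length.out = termination_min)
    )
  })
  list(records = records, ocular = ocular, entropy = entropy, lane = lane)
}

test_that("the bin table is the full crossing with missing post-termination bins", {
  st <- mk_small_study()
  tbl <- build_bin_table(st$records, st$ocular, st$entropy, st$lane)
  expect_equal(nrow(tbl), 2 * 2 * 24)
  miss <- tbl |> dplyr::filter(participant == "P02",
                               condition == "sleep_deprived")
  expect_true(all(is.na(miss$fixation_rate[17:24])))
  expect_false(any(is.na(miss$fixation_rate[1:16])))
  expect_equal(sum(!tbl$observed), 8)
})

test_that("mismatched keys are reported with the offending identity", {
  st <- mk_small_study()
  broken <- st$ocular |> dplyr::filter(!(participant == "P02" &
                                           condition == "rested"))
  expect_error(
    build_bin_table(st$records, broken, st$entropy, st$lane),
    "P02 rested"
  )
})

test_that("LOCF carries the last observed bin forward and flags it", {
  st <- mk_small_study()
  tbl <- build_bin_table(st$records, st$ocular, st$entropy, st$lane)
  imp <- impute_locf(tbl)
  expect_equal(nrow(imp), 96)
  expect_false(anyNA(imp$Hs_norm))
  expect_equal(sum(imp$imputed), 8)

  filled <- imp |> dplyr::filter(participant == "P02",
                                 condition == "sleep_deprived")
  expect_equal(filled$Hs_norm[17:24], rep(0.2 + 0.005 * 16, 8))
  expect_equal(filled$fixation_rate[17:24], rep(75 - 16, 8))
  expect_true(all(filled$imputed[17:24]))

  # fully observed sessions are untouched and idempotence holds
  expect_equal(
    imp |> dplyr::filter(observed) |> dplyr::select(-imputed),
    tbl |> dplyr::filter(observed) |> dplyr::select(-imputed)
  )
  expect_equal(impute_locf(imp), imp)
})

test_that("imputation errors when a session has zero observed bins", {
  st <- mk_small_study()
  tbl <- build_bin_table(st$records, st$ocular, st$entropy, st$lane)
  tbl$observed[tbl$participant == "P01" & tbl$condition == "rested"] <- FALSE
  expect_error(impute_locf(tbl), "zero observed bins")
})

test_that("lane events are conserved between minute series and observed bins", {
  st <- mk_small_study()
  tbl <- build_bin_table(st$records, st$ocular, st$entropy, st$lane)
  per_session_bins <- tbl |>
    dplyr::filter(observed) |>
    dplyr::group_by(participant, condition) |>
    dplyr::summarise(total = sum(lane_events), .groups = "drop")
  per_session_minutes <- st$lane |>
    dplyr::group_by(participant, condition) |>
    dplyr::summarise(total = sum(count), .groups = "drop")
  expect_equal(per_session_bins, per_session_minutes)
})

test_that("the minute table covers driven minutes only and binarises counts", {
  withr::local_seed(31)
  records <- session_records("P01", "sleep_deprived", 77)
  n <- 77 * 60
  fx <- tibble::tibble(
    participant = "P01", condition = "sleep_deprived",
    onset_ms = sort(runif(n, 0, 77 * 60000 - 400)),
    offset_ms = NA_real_, duration_ms = 350,
    cx_px = runif(n, 200, 1000), cy_px = runif(n, 200, 700)
  ) |> dplyr::mutate(offset_ms = onset_ms + 350)
  sc <- saccade_amplitudes(fx) |>
    dplyr::mutate(participant = "P01", condition = "sleep_deprived")
  bl <- fx[0, c("participant", "condition", "onset_ms", "offset_ms",
                "duration_ms")]
  lane <- tibble::tibble(participant = "P01", condition = "sleep_deprived",
                         minute = 1:77,
                         count = rep(c(0L, 2L, 0L, 1L, 0L, 0L, 3L),
                                     length.out = 77))
  mt <- minute_table(records, fx, sc, bl, lane)
  expect_equal(nrow(mt), 77)
  expect_equal(mt$lane_departure, as.integer(lane$count >= 1))
  expect_equal(mt$driving_min, 0:76)
  expect_true(all(mt$Hs_pct >= 0 & mt$Hs_pct <= 100, na.rm = TRUE))
})
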