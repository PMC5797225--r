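#' Session records
#'
#' One row per driving session: who drove, under which condition, and for how
#' long. Sessions are capped (120 minutes by default study design); a session
#' shorter than the cap is an early termination, the event of interest for
#' the driving-duration survival analysis.
#'
#' @param participant participant identifiers.
#' @param condition `"rested"` or `"sleep_deprived"`.
#' @param termination_min driving duration in minutes, `0 <` and `<=` cap.
#' @param cap_min session cap in minutes (default 120).
#' @return tibble `participant`, `condition`, `termination_min`,
#'   `early_termination`.
#' @export
session_records <- function(participant, condition, termination_min,
                            cap_min = 120) {
  condition <- as.character(condition)
  bad <- setdiff(unique(condition), c("rested", "sleep_deprived"))
  if (length(bad) > 0) {
    abort(paste0("unknown condition(s): ", paste(bad, collapse = ", ")))
  }
  if (any(termination_min <= 0 | termination_min > cap_min)) {
    abort("termination_min must lie in (0, cap_min]")
  }
  tibble(
    participant = as.character(participant),
    condition = condition,
    termination_min = as.numeric(termination_min),
    early_termination = termination_min < cap_min
  )
}

#' Read and write per-minute lane-departure CSV files
#'
#' Dialect: `participant,condition,minute,count` where `minute` is the
#' 1-based index of the driving minute and `count` the number of lane
#' departure events recorded in it.
#'
#' @param path file path.
#' @param lane lane-event tibble.
#' @export
read_lane_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    participant = readr::col_character(),
    condition = readr::col_character(),
    minute = readr::col_integer(),
    count = readr::col_integer()
  ))
}

#' @rdname read_lane_csv
#' @export
write_lane_csv <- function(lane, path) {
  readr::write_csv(lane, path)
  invisible(path)
}

# measure columns carried through binning and imputation
bin_measure_cols <- function() {
  c("blink_rate", "blink_duration_ms", "fixation_rate",
    "fixation_duration_ms", "saccade_amplitude_deg",
    "Hs_norm", "Hs_pct", "Ht_norm", "Ht_pct", "lane_events")
}

check_keys <- function(records, tbl, what) {
  need <- paste(records$participant, records$condition)
  have <- unique(paste(tbl$participant, tbl$condition))
  missing_keys <- setdiff(need, have)
  if (length(missing_keys) > 0) {
    abort(paste0(
      "no ", what, " rows for participant x condition: ",
      paste(missing_keys, collapse = "; ")
    ))
  }
  stray <- setdiff(have, need)
  if (length(stray) > 0) {
    abort(paste0(
      what, " rows for unknown participant x condition: ",
      paste(stray, collapse = "; ")
    ))
  }
  invisible(TRUE)
}

#' Per-bin ocular summaries for a study table of events
#'
#' Applies [summarize_ocular()] over consecutive time bins of every session.
#' The final bin of an early-terminated session is partial: rates are
#' normalised by the actually driven bin length.
#'
#' @param records [session_records()] table.
#' @param fixations,saccades,blinks study-level event tibbles carrying
#'   `participant` and `condition` key columns.
#' @param bin_length_min bin length in minutes.
#' @return tibble keyed by `participant`, `condition`, `bin_index` with the
#'   [summarize_ocular()] columns.
#' @export
ocular_bin_summaries <- function(records, fixations, saccades, blinks,
                                 bin_length_min = 5) {
  purrr::pmap_dfr(records, function(participant, condition, termination_min,
                                    early_termination, ...) {
    f <- filter(fixations, .data$participant == !!participant,
                .data$condition == !!condition)
    s <- filter(saccades, .data$participant == !!participant,
                .data$condition == !!condition)
    b <- filter(blinks, .data$participant == !!participant,
                .data$condition == !!condition)
    n_bins <- ceiling(termination_min / bin_length_min)
    purrr::map_dfr(seq_len(n_bins), function(k) {
      lo <- (k - 1) * bin_length_min * 60000
      hi <- min(k * bin_length_min, termination_min) * 60000
      summarize_ocular(f, s, b, lo, hi) |>
        mutate(participant = participant, condition = condition,
               bin_index = k, .before = 1)
    })
  })
}

#' Assemble the per-bin analysis table
#'
#' Builds the full crossing participants x conditions x bins up to the
#' session cap, fills observed bins from the ocular, entropy, and
#' lane-departure inputs, and leaves bins after a session's termination
#' missing for [impute_locf()]. Lane-departure counts are aggregated from
#' the per-minute series into bins by minute index.
#'
#' @param records [session_records()] table.
#' @param ocular output of [ocular_bin_summaries()].
#' @param entropy study-level [entropy_timeseries()] rows keyed by
#'   `participant`, `condition`, `bin_index`.
#' @param lane per-minute lane-event tibble
#'   (`participant, condition, minute, count`).
#' @param bin_length_min bin length in minutes (default 5).
#' @param cap_min session cap in minutes (default 120).
#' @return tibble with one row per participant x condition x bin:
#'   keys, `bin_start_min`, `observed`, `imputed`, ocular measures,
#'   `Hs_norm`, `Hs_pct`, `Ht_norm`, `Ht_pct`, `lane_events`.
#' @export
build_bin_table <- function(records, ocular, entropy, lane,
                            bin_length_min = 5, cap_min = 120) {
  check_keys(records, ocular, "ocular summary")
  check_keys(records, entropy, "entropy")
  check_keys(records, lane, "lane event")
  n_bins <- ceiling(cap_min / bin_length_min)

  lane_bins <- lane |>
    mutate(bin_index = ceiling(.data$minute / bin_length_min)) |>
    group_by(.data$participant, .data$condition, .data$bin_index) |>
    summarise(lane_events = sum(.data$count), .groups = "drop")

  grid_tbl <- tidyr::crossing(
    records |> select("participant", "condition", "termination_min"),
    bin_index = seq_len(n_bins)
  )

  out <- grid_tbl |>
    mutate(
      bin_start_min = (.data$bin_index - 1) * bin_length_min,
      observed = .data$bin_start_min < .data$termination_min
    ) |>
    left_join(
      ocular |> select("participant", "condition", "bin_index",
                       "blink_rate", "blink_duration_ms", "fixation_rate",
                       "fixation_duration_ms", "saccade_amplitude_deg"),
      by = c("participant", "condition", "bin_index")
    ) |>
    left_join(
      entropy |> select("participant", "condition", "bin_index",
                        "Hs_norm", "Hs_pct", "Ht_norm", "Ht_pct"),
      by = c("participant", "condition", "bin_index")
    ) |>
    left_join(lane_bins, by = c("participant", "condition", "bin_index")) |>
    mutate(
      lane_events = ifelse(.data$observed & is.na(.data$lane_events),
                           0L, .data$lane_events),
      imputed = FALSE
    ) |>
    select(-"termination_min") |>
    arrange(.data$participant, .data$condition, .data$bin_index)
  out
}

#' Impute post-termination bins by last observation carried forward
#'
#' Early terminations are caused by the condition itself, so the missingness
#' is informative rather than at random; the analysis convention is to carry
#' the last observed bin's measures forward into every post-termination bin.
#' Observed rows are never altered; imputed rows are flagged, and the
#' operation is idempotent.
#'
#' @param bin_table output of [build_bin_table()].
#' @return the completed table: no missing measure cells remain, `imputed`
#'   marks carried-forward rows.
#' @export
impute_locf <- function(bin_table) {
  cols <- intersect(bin_measure_cols(), names(bin_table))
  bin_table |>
    group_by(.data$participant, .data$condition) |>
    arrange(.data$bin_index, .by_group = TRUE) |>
    group_modify(function(g, key) {
      obs <- which(g$observed)
      if (length(obs) == 0) {
        abort(paste0(
          "participant x condition with zero observed bins: ",
          paste(unlist(key), collapse = " / ")
        ))
      }
      last_obs <- max(obs)
      fill_rows <- which(!g$observed)
      if (length(fill_rows) > 0) {
        g[fill_rows, cols] <- g[last_obs, cols]
        g$imputed[fill_rows] <- TRUE
      }
      g
    }) |>
    ungroup()
}

#' Per-minute table for lane-departure prediction
#'
#' Lane departures are recorded per minute, so the prediction models work on
#' 1-minute bins: ocular summaries, entropy on a fine (30 px) grid entered on
#' the percent scale (`Hs_pct`, `Ht_pct`), and the binary outcome
#' `lane_departure = (count >= 1)`. Only driven minutes appear — imputation
#' is a device for the condition-by-time analysis, not for prediction.
#'
#' @param records [session_records()] table.
#' @param fixations,saccades,blinks study-level event tibbles with
#'   `participant`, `condition` keys.
#' @param lane per-minute lane-event tibble.
#' @param grid fine [state_grid()] for entropy (default 30 px cells).
#' @param h_max transition-entropy normalisation (see [transition_entropy()]).
#' @return tibble with one row per driven minute: keys, `minute` (1-based),
#'   `driving_min` (elapsed minutes at bin start), ocular measures,
#'   `Hs_pct`, `Ht_pct`, `lane_count`, `lane_departure` (0/1).
#' @export
minute_table <- function(records, fixations, saccades, blinks, lane,
                         grid = state_grid(30),
                         h_max = c("observed", "possible")) {
  h_max <- match.arg(h_max)
  check_keys(records, lane, "lane event")

  purrr::pmap_dfr(records, function(participant, condition, termination_min,
                                    early_termination, ...) {
    f <- filter(fixations, .data$participant == !!participant,
                .data$condition == !!condition)
    s <- filter(saccades, .data$participant == !!participant,
                .data$condition == !!condition)
    b <- filter(blinks, .data$participant == !!participant,
                .data$condition == !!condition)
    l <- filter(lane, .data$participant == !!participant,
                .data$condition == !!condition)
    ent <- entropy_timeseries(f, grid, bin_length_min = 1,
                              session_length_min = ceiling(termination_min),
                              h_max = h_max)
    n_min <- ceiling(termination_min)
    purrr::map_dfr(seq_len(n_min), function(m) {
      lo <- (m - 1) * 60000
      hi <- min(m, termination_min) * 60000
      oc <- summarize_ocular(f, s, b, lo, hi)
      cnt <- l$count[l$minute == m]
      cnt <- if (length(cnt) == 0) 0L else sum(cnt)
      tibble(
        participant = participant, condition = condition,
        minute = m, driving_min = m - 1,
        blink_rate = oc$blink_rate,
        blink_duration_ms = oc$blink_duration_ms,
        fixation_rate = oc$fixation_rate,
        fixation_duration_ms = oc$fixation_duration_ms,
        saccade_amplitude_deg = oc$saccade_amplitude_deg,
        Hs_pct = ent$Hs_pct[m], Ht_pct = ent$Ht_pct[m],
        lane_count = cnt,
        lane_departure = as.integer(cnt >= 1)
      )
    })
  })
}
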