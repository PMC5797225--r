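#' Detect fixations with the dispersion-threshold (I-DT) algorithm
#'
#' Classic Salvucci–Goldberg I-DT: a window is grown over consecutive valid
#' samples while its spatial dispersion stays within `max_dispersion_px`; a
#' window is emitted as a fixation when it also spans at least
#' `min_duration_ms`. Emitted fixations are maximal and non-overlapping, and
#' the centroid is the mean of the member sample coordinates. Invalid samples
#' (tracking loss / blinks) terminate any open window, so a blink splits a
#' fixation in two.
#'
#' Dispersion is, by default, `(max x - min x) + (max y - min y)` over the
#' window — the definition used by the classic algorithm. Vendor analysis
#' suites do not document their exact variant, so the maximum pairwise
#' Euclidean distance is available as an alternative.
#'
#' @param samples gaze-sample tibble (see [gaze_samples()]), time-sorted.
#' @param min_duration_ms minimum fixation span in ms (default 80).
#' @param max_dispersion_px maximum window dispersion in px (default 100).
#' @param dispersion `"range_sum"` (default) or `"max_pairwise"`.
#' @return tibble of fixation events: `onset_ms`, `offset_ms`, `duration_ms`,
#'   `cx_px`, `cy_px`, `n_samples`.
#' @examples
#' smp <- gaze_samples(seq(0, 180, by = 20), rep(100, 10), rep(100, 10))
#' detect_fixations(smp)
#' @export
detect_fixations <- function(samples, min_duration_ms = 80,
                             max_dispersion_px = 100,
                             dispersion = c("range_sum", "max_pairwise")) {
  dispersion <- match.arg(dispersion)
  validate_gaze_samples(samples)
  stopifnot(min_duration_ms > 0, max_dispersion_px > 0)
  if (nrow(samples) == 0) return(empty_fixations())

  m <- .idt_detect_cpp(
    samples$t_ms, samples$x_px, samples$y_px, samples$valid,
    min_duration_ms, max_dispersion_px,
    if (dispersion == "range_sum") 0L else 1L
  )
  if (nrow(m) == 0) return(empty_fixations())
  tibble(
    onset_ms = m[, 3],
    offset_ms = m[, 4],
    duration_ms = m[, 4] - m[, 3],
    cx_px = purrr::map2_dbl(m[, 1], m[, 2], ~ mean(samples$x_px[.x:.y])),
    cy_px = purrr::map2_dbl(m[, 1], m[, 2], ~ mean(samples$y_px[.x:.y])),
    n_samples = as.integer(m[, 5])
  )
}

empty_fixations <- function() {
  tibble(
    onset_ms = numeric(), offset_ms = numeric(), duration_ms = numeric(),
    cx_px = numeric(), cy_px = numeric(), n_samples = integer()
  )
}

#' Detect blinks as maximal runs of invalid samples
#'
#' Each maximal run of samples with `valid = FALSE` becomes one blink event.
#' Onset is the first invalid sample; offset is the first valid sample after
#' the run (the eye is closed until tracking resumes), so a run of 5 invalid
#' samples at 20 ms spacing spans 100 ms. A run ending at the recording's
#' end is closed one median sample interval after its last sample.
#'
#' @inheritParams detect_fixations
#' @return tibble of blink events: `onset_ms`, `offset_ms`, `duration_ms`.
#' @export
detect_blinks <- function(samples) {
  validate_gaze_samples(samples)
  if (nrow(samples) == 0 || !any(!samples$valid)) return(empty_blinks())
  r <- rle(!samples$valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  inv <- which(r$values)
  step <- if (nrow(samples) > 1) stats::median(diff(samples$t_ms)) else 0
  off_idx <- ends[inv] + 1
  offsets <- ifelse(off_idx <= nrow(samples),
                    samples$t_ms[pmin(off_idx, nrow(samples))],
                    samples$t_ms[ends[inv]] + step)
  tibble(
    onset_ms = samples$t_ms[starts[inv]],
    offset_ms = offsets
  ) |>
    mutate(duration_ms = .data$offset_ms - .data$onset_ms)
}

empty_blinks <- function() {
  tibble(onset_ms = numeric(), offset_ms = numeric(), duration_ms = numeric())
}

#' Filter blinks by maximum duration
#'
#' Blinks longer than `max_duration_ms` (default 300 ms, boundary inclusive)
#' are removed from blink statistics: prolonged eyelid closures are candidate
#' microsleep epochs, not ordinary blinks, and would otherwise contaminate
#' blink-duration summaries. The excluded events are attached to the result
#' as the `"microsleeps"` attribute so they remain available for inspection.
#'
#' @param blinks blink-event tibble from [detect_blinks()].
#' @param max_duration_ms retention threshold in ms; events with
#'   `duration_ms <= max_duration_ms` are kept.
#' @return the retained blinks, order preserved, with excluded events in
#'   `attr(, "microsleeps")`.
#' @export
filter_blinks <- function(blinks, max_duration_ms = 300) {
  keep <- blinks$duration_ms <= max_duration_ms
  out <- blinks[keep, , drop = FALSE]
  attr(out, "microsleeps") <- as_tibble(blinks[!keep, , drop = FALSE])
  out
}

#' Saccade amplitudes between consecutive fixations
#'
#' Each pair of consecutive fixations defines one saccade whose amplitude is
#' the Euclidean distance between the fixation centroids, converted from
#' pixels to degrees of visual angle with a linear factor. The scene-camera
#' field of view is tracker-specific, so `deg_per_px` is a parameter; the
#' default 0.05 deg/px corresponds to a wide-angle scene camera
#' (64 deg across a 1280 px frame).
#'
#' @param fixations fixation tibble from [detect_fixations()].
#' @param deg_per_px degrees of visual angle per scene pixel (> 0).
#' @return tibble of saccade events: `onset_ms` (offset of the leading
#'   fixation), `offset_ms` (onset of the trailing fixation), `amplitude_deg`.
#'   Fewer than two fixations give an empty table.
#' @export
saccade_amplitudes <- function(fixations, deg_per_px = 0.05) {
  stopifnot(deg_per_px > 0)
  n <- nrow(fixations)
  if (n < 2) {
    return(tibble(onset_ms = numeric(), offset_ms = numeric(),
                  amplitude_deg = numeric()))
  }
  a <- fixations[-n, ]
  b <- fixations[-1, ]
  tibble(
    onset_ms = a$offset_ms,
    offset_ms = b$onset_ms,
    amplitude_deg = sqrt((b$cx_px - a$cx_px)^2 + (b$cy_px - a$cy_px)^2) * deg_per_px
  )
}

#' Per-bin ocular summary statistics
#'
#' Summarises detected events over one time bin: blink and fixation rates in
#' counts per minute, mean blink and fixation durations in ms, and mean
#' saccade amplitude in degrees. Events are assigned to the bin by onset
#' timestamp on the half-open interval `[bin_start_ms, bin_end_ms)`, so each
#' event is counted in exactly one bin of a partition. Duration/amplitude
#' means are `NA` (not zero) when the bin holds no events of that kind.
#'
#' @param fixations,saccades,blinks event tibbles for one session.
#' @param bin_start_ms,bin_end_ms bin boundaries in ms, `bin_end_ms >
#'   bin_start_ms`.
#' @return one-row tibble: `blink_rate`, `blink_duration_ms`, `fixation_rate`,
#'   `fixation_duration_ms`, `saccade_amplitude_deg`, `n_fixations`,
#'   `n_blinks`, `n_saccades`.
#' @export
summarize_ocular <- function(fixations, saccades, blinks,
                             bin_start_ms, bin_end_ms) {
  if (bin_end_ms <= bin_start_ms) {
    abort("zero- or negative-length bin: bin_end_ms must exceed bin_start_ms")
  }
  mins <- (bin_end_ms - bin_start_ms) / 60000
  in_bin <- function(ev) {
    ev[ev$onset_ms >= bin_start_ms & ev$onset_ms < bin_end_ms, , drop = FALSE]
  }
  f <- in_bin(fixations); b <- in_bin(blinks); s <- in_bin(saccades)
  mean_or_na <- function(v) if (length(v) == 0) NA_real_ else mean(v)
  tibble(
    blink_rate = nrow(b) / mins,
    blink_duration_ms = mean_or_na(b$duration_ms),
    fixation_rate = nrow(f) / mins,
    fixation_duration_ms = mean_or_na(f$duration_ms),
    saccade_amplitude_deg = mean_or_na(s$amplitude_deg),
    n_fixations = nrow(f),
    n_blinks = nrow(b),
    n_saccades = nrow(s)
  )
}

#' Read and write oculomotor event CSV files
#'
#' All event kinds share one dialect:
#' `kind,onset_ms,offset_ms,duration_ms,cx_px,cy_px,amplitude_deg`, with
#' empty cells where a field does not apply to the kind.
#'
#' @param path file path.
#' @param fixations,saccades,blinks event tibbles (any may be empty).
#' @return `read_events_csv()` returns a list with elements `fixations`,
#'   `saccades`, `blinks`; `write_events_csv()` returns `path` invisibly.
#' @export
write_events_csv <- function(fixations, saccades, blinks, path) {
  rows <- bind_rows(
    mutate(fixations, kind = "fixation"),
    mutate(saccades, kind = "saccade"),
    mutate(blinks, kind = "blink")
  )
  cols <- c("kind", "onset_ms", "offset_ms", "duration_ms",
            "cx_px", "cy_px", "amplitude_deg")
  for (cl in setdiff(cols, names(rows))) rows[[cl]] <- NA_real_
  readr::write_csv(rows[cols], path, na = "")
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  rows <- readr::read_csv(path, col_types = readr::cols(
    kind = readr::col_character(), .default = readr::col_double()
  ))
  list(
    fixations = rows |>
      filter(.data$kind == "fixation") |>
      select("onset_ms", "offset_ms", "duration_ms", "cx_px", "cy_px"),
    saccades = rows |>
      filter(.data$kind == "saccade") |>
      select("onset_ms", "offset_ms", "amplitude_deg"),
    blinks = rows |>
      filter(.data$kind == "blink") |>
      select("onset_ms", "offset_ms", "duration_ms")
  )
}
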