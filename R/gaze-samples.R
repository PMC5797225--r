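#' Construct a gaze-sample table
#'
#' Raw eye-tracking output is a time series of gaze positions in scene-camera
#' pixels, nominally sampled at 50 Hz (20 ms spacing) though gaps are
#' permitted. Samples flagged invalid correspond to tracking loss, which in a
#' head-mounted tracker is dominated by eyelid closure; maximal runs of
#' invalid samples are what [detect_blinks()] turns into blink events.
#'
#' @param t_ms numeric, sample timestamps in milliseconds from session start;
#'   must be strictly increasing.
#' @param x_px,y_px numeric, gaze position in scene-camera pixels (origin
#'   top-left, y increasing downward).
#' @param valid logical (or 0/1), whether the tracker reported a valid gaze
#'   position for the sample.
#' @return a tibble with columns `t_ms`, `x_px`, `y_px`, `valid`.
#' @examples
#' gaze_samples(seq(0, 180, by = 20), rep(100, 10), rep(100, 10))
#' @export
gaze_samples <- function(t_ms, x_px, y_px, valid = TRUE) {
  n <- length(t_ms)
  smp <- tibble(
    t_ms = as.numeric(t_ms),
    x_px = as.numeric(x_px),
    y_px = as.numeric(y_px),
    valid = rep_len(as.logical(valid), n)
  )
  validate_gaze_samples(smp)
  smp
}

validate_gaze_samples <- function(samples) {
  req <- c("t_ms", "x_px", "y_px", "valid")
  missing_cols <- setdiff(req, names(samples))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "gaze samples are missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(samples) > 1 && any(diff(samples$t_ms) <= 0)) {
    abort("gaze sample timestamps must be strictly increasing (malformed session)")
  }
  invisible(samples)
}

#' Read and write gaze-sample CSV files
#'
#' The on-disk dialect is a UTF-8 CSV with header `t_ms,x_px,y_px,valid`
#' and `valid` coded 0/1.
#'
#' @param path file path.
#' @param samples a gaze-sample tibble (see [gaze_samples()]).
#' @return `read_gaze_csv()` returns the sample tibble; `write_gaze_csv()`
#'   returns `path` invisibly.
#' @export
read_gaze_csv <- function(path) {
  smp <- readr::read_csv(
    path,
    col_types = readr::cols(
      t_ms = readr::col_double(),
      x_px = readr::col_double(),
      y_px = readr::col_double(),
      valid = readr::col_integer()
    )
  )
  smp$valid <- smp$valid != 0L
  validate_gaze_samples(smp)
  smp
}

#' @rdname read_gaze_csv
#' @export
write_gaze_csv <- function(samples, path) {
  validate_gaze_samples(samples)
  out <- samples
  out$valid <- as.integer(out$valid)
  readr::write_csv(out, path)
  invisible(path)
}
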