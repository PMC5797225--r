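#' Spatial state grid for fixation discretisation
#'
#' Gaze entropy is computed over a discretised visual field: the scene frame
#' is tiled with square cells ("state spaces") and each fixation is assigned
#' to the cell containing its centroid. A 100 px grid is the conventional
#' resolution for condition and time-course analyses over 5-minute bins; a
#' 30 px grid gives the finer spatial precision needed when entropy is
#' computed in 1-minute bins for lane-departure prediction.
#'
#' @param bin_size_px cell edge length in px (> 0).
#' @param frame_w_px,frame_h_px scene-frame extent in px.
#' @return a `state_grid` object.
#' @examples
#' state_grid(100)
#' state_grid(30)
#' @export
state_grid <- function(bin_size_px, frame_w_px = 1280, frame_h_px = 960) {
  stopifnot(bin_size_px > 0, frame_w_px > 0, frame_h_px > 0)
  structure(
    list(bin_size_px = bin_size_px,
         frame_w_px = frame_w_px, frame_h_px = frame_h_px),
    class = "state_grid"
  )
}

#' @export
print.state_grid <- function(x, ...) {
  cat(sprintf(
    "<state_grid> %g px cells over %g x %g px frame (%d x %d cells)\n",
    x$bin_size_px, x$frame_w_px, x$frame_h_px,
    ceiling(x$frame_w_px / x$bin_size_px),
    ceiling(x$frame_h_px / x$bin_size_px)
  ))
  invisible(x)
}

#' Discretise fixation centroids onto a state grid
#'
#' Cell indices are `(floor(x / bin_size), floor(y / bin_size))` with
#' half-open cell intervals, so a centroid exactly on a cell boundary belongs
#' to the higher-indexed cell. Centroids outside the frame are clamped to the
#' boundary cell with a warning (they arise only from tracker noise at the
#' frame edge).
#'
#' @param fixations fixation tibble with `cx_px`, `cy_px` (order preserved).
#' @param grid a [state_grid()].
#' @return the input with integer columns `cell_x`, `cell_y` and a combined
#'   state label `cell` appended; one row per fixation.
#' @export
discretize_fixations <- function(fixations, grid) {
  stopifnot(inherits(grid, "state_grid"))
  if (nrow(fixations) == 0) {
    out <- fixations
    out$cell_x <- integer()
    out$cell_y <- integer()
    out$cell <- character()
    return(out)
  }
  nx <- ceiling(grid$frame_w_px / grid$bin_size_px)
  ny <- ceiling(grid$frame_h_px / grid$bin_size_px)
  if (any(fixations$cx_px < 0 | fixations$cx_px >= grid$frame_w_px |
            fixations$cy_px < 0 | fixations$cy_px >= grid$frame_h_px)) {
    warn("fixation centroid(s) outside the frame; clamped to boundary cells")
  }
  cx <- pmin(pmax(floor(fixations$cx_px / grid$bin_size_px), 0), nx - 1)
  cy <- pmin(pmax(floor(fixations$cy_px / grid$bin_size_px), 0), ny - 1)
  out <- fixations
  out$cell_x <- as.integer(cx)
  out$cell_y <- as.integer(cy)
  out$cell <- paste(out$cell_x, out$cell_y, sep = ",")
  out
}

as_state_vector <- function(states) {
  if (is.data.frame(states)) {
    if (!"cell" %in% names(states)) {
      abort("expected a `cell` column (output of discretize_fixations())")
    }
    states <- states$cell
  }
  as.character(states)
}

entropy_result <- function(H, Hmax, n, degenerate = FALSE) {
  Hnorm <- if (Hmax > 0) H / Hmax else 0
  tibble(
    H_bits = H, H_max_bits = Hmax, H_norm = Hnorm, H_pct = 100 * Hnorm,
    n_fixations = n, degenerate = degenerate
  )
}

#' Stationary gaze entropy
#'
#' Shannon entropy of the spatial distribution of fixations over occupied
#' grid cells:
#' \deqn{H_s = -\sum_i p(i) \log_2 p(i)}
#' where `p(i)` is the proportion of the bin's fixations landing in cell `i`.
#' Cells not occupied by at least one fixation are excluded (the logarithm of
#' zero is undefined and an empty cell carries no probability mass). The
#' value is normalised by the maximum attainable entropy,
#' `H_max = log2(number of occupied cells)`, reached when fixations are
#' spread evenly over the occupied cells; `H_norm = H / H_max` lies in
#' `[0, 1]` (defined as 0 when a single cell is occupied) and `H_pct` is the
#' same value on a 0–100 scale, the scale used when entropy enters
#' odds-ratio models "per 1% increase".
#'
#' @param states a state sequence: either the tibble from
#'   [discretize_fixations()] or a vector of cell labels, one per fixation,
#'   in temporal order.
#' @return one-row tibble: `H_bits`, `H_max_bits`, `H_norm`, `H_pct`,
#'   `n_fixations`, `degenerate`.
#' @examples
#' stationary_entropy(c("a", "b", "c", "d"))   # uniform: H = 2 bits, H_norm = 1
#' stationary_entropy(c("a", "a", "a"))        # single cell: H = 0
#' @export
stationary_entropy <- function(states) {
  s <- as_state_vector(states)
  if (length(s) == 0) {
    abort("empty state sequence: stationary entropy needs at least one fixation")
  }
  p <- as.numeric(table(s))
  p <- p / sum(p)
  H <- -sum(p * log2(p))            # p > 0 by construction (0 log 0 == 0)
  entropy_result(H, log2(length(p)), length(s), degenerate = length(p) == 1)
}

#' Gaze transition entropy
#'
#' Conditional entropy of first-order Markov transitions between fixation
#' cells:
#' \deqn{H_t = -\sum_i p(i) \sum_{j \ne i} p(j|i) \log_2 p(j|i)}
#' Transition counts come from consecutive fixation pairs; transitions within
#' the same cell (self-transitions) are excluded and each origin row is
#' renormalised over destinations `j != i` so it is a proper distribution.
#' The outer weight `p(i)` is the stationary distribution of fixation
#' locations — the empirical fixation proportions over the whole bin, not
#' the Markov-chain invariant vector. `H_max` is `log2` of the number of
#' distinct observed between-cell transitions, so `H_norm = 1` is attainable;
#' a scanpath that never leaves a cell has no valid transitions and is
#' returned as 0 entropy with `H_max = 0` and `degenerate = TRUE`.
#'
#' High transition entropy means scanning order is unpredictable given the
#' current gaze location — a more random, less structured scanpath.
#'
#' @inheritParams stationary_entropy
#' @param h_max normalisation convention: `"observed"` (default) takes
#'   `log2` of the number of distinct observed between-cell transitions;
#'   `"possible"` takes `log2(k * (k - 1))` over the `k` occupied cells,
#'   i.e. all orderable between-cell pairs whether seen or not.
#' @return one-row tibble: `H_bits`, `H_max_bits`, `H_norm`, `H_pct`,
#'   `n_fixations`, `degenerate`.
#' @examples
#' transition_entropy(c("a", "b", "a", "b", "a"))  # deterministic: 0 bits
#' @export
transition_entropy <- function(states, h_max = c("observed", "possible")) {
  h_max <- match.arg(h_max)
  s <- as_state_vector(states)
  n <- length(s)
  if (n < 2) return(entropy_result(0, 0, n, degenerate = TRUE))

  from <- s[-n]; to <- s[-1]
  between <- from != to
  if (!any(between)) return(entropy_result(0, 0, n, degenerate = TRUE))
  from <- from[between]; to <- to[between]

  # stationary weights from all fixations in the bin
  p_i <- table(s) / n

  H <- 0
  for (i in unique(from)) {
    dest <- to[from == i]
    q <- as.numeric(table(dest))
    q <- q / sum(q)
    H <- H + as.numeric(p_i[[i]]) * (-sum(q * log2(q)))
  }
  n_valid <- if (h_max == "observed") {
    nrow(unique(cbind(from, to)))
  } else {
    k <- length(unique(s))
    k * (k - 1)
  }
  entropy_result(H, log2(n_valid), n, degenerate = FALSE)
}

#' Entropy time series over consecutive bins
#'
#' Partitions the session `[0, session_length_min)` into consecutive
#' half-open bins of `bin_length_min` minutes, discretises the fixations of
#' each bin on `grid`, and computes both stationary and transition entropy
#' per bin. Bins containing no fixations are returned flagged missing
#' (`missing = TRUE`, entropies `NA`) so the caller can decide on imputation.
#' `Hs_per_min` / `Ht_per_min` are the normalised entropies divided by the
#' bin length in minutes (the per-minute reporting convention).
#'
#' @param fixations fixation tibble for one session.
#' @param grid a [state_grid()].
#' @param bin_length_min bin length in minutes (> 0).
#' @param session_length_min total session span in minutes; defaults to the
#'   last fixation offset rounded up to a whole bin.
#' @param h_max transition-entropy normalisation (see [transition_entropy()]).
#' @return tibble with one row per bin: `bin_index` (1-based),
#'   `bin_start_min`, `n_fixations`, `Hs_bits`, `Hs_max`, `Hs_norm`,
#'   `Hs_pct`, `Ht_bits`, `Ht_max`, `Ht_norm`, `Ht_pct`, `Hs_per_min`,
#'   `Ht_per_min`, `missing`.
#' @export
entropy_timeseries <- function(fixations, grid, bin_length_min = 5,
                               session_length_min = NULL,
                               h_max = c("observed", "possible")) {
  h_max <- match.arg(h_max)
  stopifnot(bin_length_min > 0)
  if (is.null(session_length_min)) {
    session_length_min <- if (nrow(fixations) == 0) {
      bin_length_min
    } else {
      ceiling(max(fixations$offset_ms) / 60000 / bin_length_min) * bin_length_min
    }
  }
  n_bins <- ceiling(session_length_min / bin_length_min)
  disc <- discretize_fixations(fixations, grid)

  purrr::map_dfr(seq_len(n_bins), function(b) {
    lo <- (b - 1) * bin_length_min * 60000
    hi <- b * bin_length_min * 60000
    cells <- disc$cell[disc$onset_ms >= lo & disc$onset_ms < hi]
    if (length(cells) == 0) {
      return(tibble(
        bin_index = b, bin_start_min = (b - 1) * bin_length_min,
        n_fixations = 0L,
        Hs_bits = NA_real_, Hs_max = NA_real_, Hs_norm = NA_real_,
        Hs_pct = NA_real_,
        Ht_bits = NA_real_, Ht_max = NA_real_, Ht_norm = NA_real_,
        Ht_pct = NA_real_,
        Hs_per_min = NA_real_, Ht_per_min = NA_real_, missing = TRUE
      ))
    }
    hs <- stationary_entropy(cells)
    ht <- transition_entropy(cells, h_max = h_max)
    tibble(
      bin_index = b, bin_start_min = (b - 1) * bin_length_min,
      n_fixations = length(cells),
      Hs_bits = hs$H_bits, Hs_max = hs$H_max_bits, Hs_norm = hs$H_norm,
      Hs_pct = hs$H_pct,
      Ht_bits = ht$H_bits, Ht_max = ht$H_max_bits, Ht_norm = ht$H_norm,
      Ht_pct = ht$H_pct,
      Hs_per_min = hs$H_norm / bin_length_min,
      Ht_per_min = ht$H_norm / bin_length_min,
      missing = FALSE
    )
  })
}

#' Write an entropy time-series CSV
#'
#' Dialect: `participant,condition,bin_index,bin_start_min,n_fixations,
#' Hs_bits,Hs_max,Hs_norm,Ht_bits,Ht_max,Ht_norm,Hs_per_min,Ht_per_min`.
#'
#' @param entropy a tibble of [entropy_timeseries()] rows carrying
#'   `participant` and `condition` columns.
#' @param path file path.
#' @export
write_entropy_csv <- function(entropy, path) {
  cols <- c("participant", "condition", "bin_index", "bin_start_min",
            "n_fixations", "Hs_bits", "Hs_max", "Hs_norm",
            "Ht_bits", "Ht_max", "Ht_norm", "Hs_per_min", "Ht_per_min")
  readr::write_csv(entropy[intersect(cols, names(entropy))], path, na = "")
  invisible(path)
}
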