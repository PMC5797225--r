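#' Generator parameters for synthetic driving sessions
#'
#' Returns the parameter set of the synthetic-session generator. Defaults
#' emulate a two-condition (rested vs sleep-deprived) within-subject driving
#' study: condition means for fixation rate, fixation duration, blink rate,
#' blink duration and saccade amplitude; a spatial gaze model (road-ahead
#' core plus six fixed glance targets with first-order Markov glance
#' dynamics) whose dispersion and glance structure set stationary and
#' transition entropy; time-on-task drift of the fixation and blink rates;
#' early-termination hazard in the sleep-deprived condition; and a
#' lane-departure model with known logistic coefficients (condition odds
#' ratio 3.20, odds ratio 1.014 per minute driven, odds ratio 1.07 per 1%
#' stationary entropy) plus a Poisson count model with condition rate
#' ratio 3.79.
#'
#' Components of the spatial model: with probability `glance_prob` a fixation
#' leaves the road-ahead core for a glance target (mirrors, instrument
#' cluster, periphery); from a target the gaze returns to the core with
#' probability `return_prob`, otherwise it hops to another target. Sleep
#' deprivation widens the core (`sigma_core_px`), flattens the glance-target
#' distribution and lowers `return_prob`, which raises both stationary and
#' transition entropy; `dispersion_scale` multiplies both sigmas and is the
#' single knob for entropy level. `glance_prob` values are calibrated so the
#' mean saccade amplitude at 0.05 deg/px matches the condition means.
#'
#' @param rested,sleep_deprived named lists overriding per-condition defaults.
#' @param shared named list overriding shared defaults.
#' @return object of class `gaze_params`.
#' @export
gaze_params <- function(rested = list(), sleep_deprived = list(),
                        shared = list()) {
  def_shared <- list(
    frame_w_px = 1280, frame_h_px = 960, sample_hz = 50,
    noise_sd_px = 6, gap_jitter_px = 100,
    cap_min = 120, block_min = 5,
    fix_sdlog = 0.30, fix_trunc_ms = c(120, 2000),
    blink_sdlog = 0.25, blink_trunc_ms = c(20, 1000),
    blink_filter_ms = 300,
    drift_gain = 0.3,
    glance_targets = rbind(
      c(100, 150), c(1180, 150), c(100, 810), c(1180, 810),
      c(640, 100), c(640, 870)
    ),
    # lane-departure occurrence: logit P = intercept + condition + minute +
    # stationary entropy (percent scale, centred at hs_ref)
    lane_logistic = c(
      intercept = -2.4, condition = log(3.20),
      per_min = log(1.014), hs_pct = log(1.07)
    ),
    hs_ref = 90,
    lane_extra_mean = 0.4,  # extra events per event-minute (count = 1 + Pois)
    # lane-departure count model (Poisson intensity per minute)
    lane_poisson = list(
      base_rate_per_min = 0.15,
      rate_ratio_condition = 3.79,
      rate_ratio_per_block = c(rested = 0.98, sleep_deprived = 1.065)
    )
  )
  def_rested <- list(
    fixation_rate_per_min = 76.91, fixation_duration_ms = 561.38,
    blink_rate_per_min = 39.42, blink_duration_ms = 179.88,
    sigma_core_px = 24, sigma_target_px = 10, dispersion_scale = 1,
    glance_prob = 0.706, return_prob = 0.90,
    target_probs = c(0.06, 0.06, 0.06, 0.06, 0.38, 0.38),
    hazard_per_block = 0, min_drive_min = 30,
    drift = list(
      fixation_rate = c(63.081, 0.077),
      blink_rate = c(41.780, 0.277, -0.002)
    )
  )
  def_deprived <- list(
    fixation_rate_per_min = 60.80, fixation_duration_ms = 510.27,
    blink_rate_per_min = 52.40, blink_duration_ms = 200.75,
    sigma_core_px = 45, sigma_target_px = 18, dispersion_scale = 1,
    glance_prob = 0.733, return_prob = 0.45,
    target_probs = rep(1 / 6, 6),
    hazard_per_block = 0.06, min_drive_min = 30,
    drift = list(
      fixation_rate = c(55.829, -1.090, -0.016, -0.0001),
      blink_rate = c(30.727, 1.964, -0.033, 0.0002)
    )
  )
  p <- list(
    shared = utils::modifyList(def_shared, shared),
    rested = utils::modifyList(def_rested, rested),
    sleep_deprived = utils::modifyList(def_deprived, sleep_deprived)
  )
  for (cond in c("rested", "sleep_deprived")) {
    pc <- p[[cond]]
    if (pc$fixation_rate_per_min <= 0 || pc$blink_rate_per_min <= 0) {
      abort("rates must be positive")
    }
    if (pc$glance_prob < 0 || pc$glance_prob > 1 ||
          pc$return_prob < 0 || pc$return_prob > 1) {
      abort("glance_prob and return_prob must lie in [0, 1]")
    }
  }
  structure(p, class = "gaze_params")
}

#' @export
print.gaze_params <- function(x, ...) {
  cat("<gaze_params> synthetic-session generator parameters\n")
  for (cond in c("rested", "sleep_deprived")) {
    cat(sprintf(
      "  %-15s fix %.1f/min %.0f ms | blink %.1f/min %.0f ms | hazard %.2f\n",
      cond, x[[cond]]$fixation_rate_per_min, x[[cond]]$fixation_duration_ms,
      x[[cond]]$blink_rate_per_min, x[[cond]]$blink_duration_ms,
      x[[cond]]$hazard_per_block
    ))
  }
  invisible(x)
}

# meanlog of a lognormal truncated to [lo, hi] whose truncated mean is target
solve_trunc_lnorm_meanlog <- function(target, sdlog, lo, hi) {
  trunc_mean <- function(mu) {
    a <- (log(hi) - mu) / sdlog
    b <- (log(lo) - mu) / sdlog
    num <- stats::pnorm(a - sdlog) - stats::pnorm(b - sdlog)
    den <- stats::pnorm(a) - stats::pnorm(b)
    exp(mu + sdlog^2 / 2) * num / den
  }
  lo_mu <- log(lo * 1.001)
  hi_mu <- log(hi * 0.999)
  # the truncated mean is monotone in mu and bounded by the interval; clamp
  # infeasible targets to the nearest attainable endpoint
  if (target <= trunc_mean(lo_mu)) return(lo_mu)
  if (target >= trunc_mean(hi_mu)) return(hi_mu)
  stats::uniroot(function(mu) trunc_mean(mu) - target,
                 interval = c(lo_mu, hi_mu), tol = 1e-10)$root
}

rtrunc_lnorm <- function(n, meanlog, sdlog, lo, hi) {
  qlnorm(runif(n, plnorm(lo, meanlog, sdlog), plnorm(hi, meanlog, sdlog)),
         meanlog, sdlog)
}

polyval <- function(coefs, x) {
  out <- 0
  for (k in seq_along(coefs)) out <- out + coefs[k] * x^(k - 1)
  out
}

# multiplicative time-on-task shape: 1 at the session average, modulated by
# the measure's drift polynomial evaluated in 5-minute block units
drift_shape <- function(coefs, t_min, gain, cap_min) {
  if (is.null(coefs)) return(rep(1, length(t_min)))
  xg <- seq(0, cap_min / 5, length.out = 241)
  pbar <- mean(polyval(coefs, xg))
  pmin(pmax(1 + gain * (polyval(coefs, t_min / 5) / pbar - 1), 0.5), 1.5)
}

# first-order Markov glance chain over 0 = road-ahead core, 1..K = targets
glance_chain <- function(n, glance_prob, return_prob, target_probs) {
  state <- integer(n)
  cur <- 0L
  k <- length(target_probs)
  u <- runif(n)
  for (i in seq_len(n)) {
    if (cur == 0L) {
      if (u[i] < glance_prob) cur <- sample.int(k, 1, prob = target_probs)
    } else {
      if (u[i] < return_prob) {
        cur <- 0L
      } else {
        cur <- sample.int(k, 1, prob = target_probs)
      }
    }
    state[i] <- cur
  }
  state
}

#' Generate one synthetic driving session
#'
#' Builds a session bottom-up with known ground truth: fixation onsets from
#' a renewal process at the (time-drifting) condition rate; fixation
#' locations from the Markov glance model; blinks inserted between fixations
#' with truncated-lognormal durations (calibrated so the mean of blinks
#' passing the 300 ms filter matches the condition mean); early termination
#' drawn from a per-5-minute-block hazard after a minimum driven time; and
#' per-minute lane-departure counts from a logistic occurrence model driven
#' by condition, elapsed minutes, and the session's realised per-minute
#' stationary entropy (percent scale, 30 px grid). Optionally rasterises the
#' ground-truth events into a 50 Hz gaze-sample stream: fixation samples get
#' isotropic Gaussian noise, saccade samples interpolate between centroids,
#' blink samples are invalid.
#'
#' @param params a [gaze_params()] object.
#' @param participant participant id.
#' @param condition `"rested"` or `"sleep_deprived"`.
#' @param seed integer seed; fixed seed gives identical output.
#' @param emit_samples also rasterise the 50 Hz sample stream (default TRUE;
#'   the stream for a 120-minute session holds 360,000 rows).
#' @param rate_offset,blink_offset,duration_offset,spatial_offset
#'   multiplicative per-participant heterogeneity applied by
#'   [generate_study()]; 1 for a single session.
#' @return object of class `gaze_session`: `record` (session row),
#'   `fixations`, `blinks` (ground-truth events), `lane` (per-minute
#'   counts), `latent` (per-minute entropy driving the lane model), and
#'   `samples` (50 Hz stream or NULL).
#' @export
generate_session <- function(params, participant, condition, seed,
                             emit_samples = TRUE,
                             rate_offset = 1, blink_offset = 1,
                             duration_offset = 1, spatial_offset = 1) {
  stopifnot(inherits(params, "gaze_params"),
            condition %in% c("rested", "sleep_deprived"))
  withr::local_seed(as.integer(seed))
  sh <- params$shared
  pc <- params[[condition]]

  # --- termination ---------------------------------------------------------
  n_blocks <- ceiling(sh$cap_min / sh$block_min)
  first_risk <- floor(pc$min_drive_min / sh$block_min) + 1
  term_block <- n_blocks
  if (pc$hazard_per_block > 0) {
    for (b in seq(first_risk, n_blocks)) {
      if (runif(1) < pc$hazard_per_block) { term_block <- b; break }
    }
  }
  termination_min <- min(term_block * sh$block_min, sh$cap_min)
  term_ms <- termination_min * 60000

  # --- event timeline, block by block (drift is constant within a block) ---
  fix_meanlog <- solve_trunc_lnorm_meanlog(
    pc$fixation_duration_ms * duration_offset, sh$fix_sdlog,
    sh$fix_trunc_ms[1], sh$fix_trunc_ms[2]
  )
  blink_meanlog <- solve_trunc_lnorm_meanlog(
    pc$blink_duration_ms * duration_offset, sh$blink_sdlog,
    sh$blink_trunc_ms[1], min(sh$blink_filter_ms, sh$blink_trunc_ms[2])
  )
  blink_retention <-
    (plnorm(sh$blink_filter_ms, blink_meanlog, sh$blink_sdlog) -
       plnorm(sh$blink_trunc_ms[1], blink_meanlog, sh$blink_sdlog)) /
    (plnorm(sh$blink_trunc_ms[2], blink_meanlog, sh$blink_sdlog) -
       plnorm(sh$blink_trunc_ms[1], blink_meanlog, sh$blink_sdlog))
  e_fix <- pc$fixation_duration_ms * duration_offset
  e_blink_gen <- {
    a <- (log(sh$blink_trunc_ms[2]) - blink_meanlog) / sh$blink_sdlog
    b <- (log(sh$blink_trunc_ms[1]) - blink_meanlog) / sh$blink_sdlog
    exp(blink_meanlog + sh$blink_sdlog^2 / 2) *
      (stats::pnorm(a - sh$blink_sdlog) - stats::pnorm(b - sh$blink_sdlog)) /
      (stats::pnorm(a) - stats::pnorm(b))
  }

  fo <- list(); fd <- list(); bo <- list(); bd <- list()
  cursor <- 0
  for (b in seq_len(term_block)) {
    block_end <- min(b * sh$block_min, termination_min) * 60000
    mid_min <- (b - 0.5) * sh$block_min
    rate <- pc$fixation_rate_per_min * rate_offset *
      drift_shape(pc$drift$fixation_rate, mid_min, sh$drift_gain, sh$cap_min)
    brate <- pc$blink_rate_per_min * blink_offset *
      drift_shape(pc$drift$blink_rate, mid_min, sh$drift_gain, sh$cap_min)
    p_blink <- min(brate / blink_retention / rate, 0.98)
    cycle_ms <- 60000 / rate
    gap_base <- max(60, cycle_ms - e_fix - p_blink * e_blink_gen)

    n_draw <- ceiling((block_end - cursor) / cycle_ms * 1.7) + 20
    dur <- rtrunc_lnorm(n_draw, fix_meanlog, sh$fix_sdlog,
                        sh$fix_trunc_ms[1], sh$fix_trunc_ms[2])
    has_blink <- runif(n_draw) < p_blink
    bl_dur <- ifelse(
      has_blink,
      rtrunc_lnorm(n_draw, blink_meanlog, sh$blink_sdlog,
                   sh$blink_trunc_ms[1], sh$blink_trunc_ms[2]),
      0
    )
    gap <- gap_base * runif(n_draw, 0.6, 1.4)
    cyc <- dur + gap + bl_dur
    onset <- cursor + c(0, cumsum(cyc[-n_draw]))
    keep <- onset + dur <= block_end
    if (!any(keep)) next
    onset <- onset[keep]; dur2 <- dur[keep]
    gap2 <- gap[keep]; hb <- has_blink[keep]; bld <- bl_dur[keep]
    fo[[b]] <- onset
    fd[[b]] <- dur2
    bstart <- onset + dur2 + 0.5 * gap2
    keep_bl <- hb & (bstart + bld) < block_end
    bo[[b]] <- bstart[keep_bl]
    bd[[b]] <- bld[keep_bl]
    cursor <- max(onset + dur2 + gap2 + bld)
  }
  fix_onset <- unlist(fo) %||% numeric()
  fix_dur <- unlist(fd) %||% numeric()
  blink_onset <- unlist(bo) %||% numeric()
  blink_dur <- unlist(bd) %||% numeric()
  nf <- length(fix_onset)
  if (nf < 2) abort("degenerate session: fewer than 2 fixations generated")

  # --- fixation locations: Markov glance chain -----------------------------
  st <- glance_chain(nf, pc$glance_prob, pc$return_prob, pc$target_probs)
  ctr <- c(sh$frame_w_px / 2, sh$frame_h_px / 2)
  tg <- sh$glance_targets
  mx <- ifelse(st == 0, ctr[1], tg[pmax(st, 1), 1])
  my <- ifelse(st == 0, ctr[2], tg[pmax(st, 1), 2])
  ssd <- ifelse(st == 0, pc$sigma_core_px, pc$sigma_target_px) *
    pc$dispersion_scale * spatial_offset
  cx <- pmin(pmax(rnorm(nf, mx, ssd), 1), sh$frame_w_px - 1)
  cy <- pmin(pmax(rnorm(nf, my, ssd), 1), sh$frame_h_px - 1)

  fixations <- tibble(
    participant = as.character(participant), condition = condition,
    onset_ms = fix_onset, offset_ms = fix_onset + fix_dur,
    duration_ms = fix_dur, cx_px = cx, cy_px = cy
  )
  blinks <- tibble(
    participant = as.character(participant), condition = condition,
    onset_ms = blink_onset, offset_ms = blink_onset + blink_dur,
    duration_ms = blink_dur
  )

  # --- latent per-minute stationary entropy (30 px grid, percent scale) ----
  grid30 <- state_grid(30, sh$frame_w_px, sh$frame_h_px)
  ent <- entropy_timeseries(fixations, grid30, bin_length_min = 1,
                            session_length_min = ceiling(termination_min))
  hs_pct <- ent$Hs_pct
  if (anyNA(hs_pct)) {  # minutes without fixations: carry forward / reference
    for (i in seq_along(hs_pct)) {
      if (is.na(hs_pct[i])) hs_pct[i] <- if (i > 1) hs_pct[i - 1] else sh$hs_ref
    }
  }

  # --- lane-departure events ------------------------------------------------
  n_min <- ceiling(termination_min)
  beta <- sh$lane_logistic
  eta <- beta[["intercept"]] +
    beta[["condition"]] * (condition == "sleep_deprived") +
    beta[["per_min"]] * (seq_len(n_min) - 1) +
    beta[["hs_pct"]] * (hs_pct - sh$hs_ref)
  occur <- rbinom(n_min, 1, plogis(eta))
  count <- occur * (1L + rpois(n_min, sh$lane_extra_mean))
  lane <- tibble(
    participant = as.character(participant), condition = condition,
    minute = seq_len(n_min), count = as.integer(count)
  )

  samples <- if (emit_samples) {
    rasterize_samples(fixations, blinks, term_ms, sh)
  } else {
    NULL
  }

  structure(
    list(
      record = session_records(participant, condition, termination_min,
                               cap_min = sh$cap_min),
      fixations = fixations, blinks = blinks, lane = lane,
      latent = tibble(minute = seq_len(n_min), Hs_pct = hs_pct,
                      p_event = plogis(eta)),
      samples = samples, params = params
    ),
    class = "gaze_session"
  )
}

#' @export
print.gaze_session <- function(x, ...) {
  cat(sprintf(
    "<gaze_session> %s / %s: %.0f min, %d fixations, %d blinks, %d lane events\n",
    x$record$participant, x$record$condition, x$record$termination_min,
    nrow(x$fixations), nrow(x$blinks), sum(x$lane$count)
  ))
  invisible(x)
}

# rasterise ground-truth events into a 50 Hz sample stream
rasterize_samples <- function(fixations, blinks, term_ms, sh) {
  step <- 1000 / sh$sample_hz
  t <- seq(0, term_ms - step, by = step)
  nf <- nrow(fixations)

  # piecewise intervals: fixation / blink / saccade (everything else)
  fi <- findInterval(t, fixations$onset_ms)
  in_fix <- fi >= 1 & t < fixations$offset_ms[pmax(fi, 1)]
  bi <- findInterval(t, blinks$onset_ms)
  in_blink <- nrow(blinks) > 0 & bi >= 1 &
    t < c(blinks$offset_ms, 0)[pmax(bi, 1)]

  # position: fixations jitter around the centroid; gaps interpolate between
  # the bounding centroids
  prev <- pmax(fi, 1)
  nxt <- pmin(fi + 1, nf)
  t0 <- fixations$offset_ms[prev]
  t1 <- fixations$onset_ms[nxt]
  frac <- ifelse(t1 > t0, pmin(pmax((t - t0) / (t1 - t0), 0), 1), 0)
  x <- ifelse(in_fix, fixations$cx_px[prev],
              fixations$cx_px[prev] +
                frac * (fixations$cx_px[nxt] - fixations$cx_px[prev]))
  y <- ifelse(in_fix, fixations$cy_px[prev],
              fixations$cy_px[prev] +
                frac * (fixations$cy_px[nxt] - fixations$cy_px[prev]))
  # fixation samples carry tracker noise; gap (saccade) samples are
  # oculomotorically unstable, so they scatter on a wide ring around the
  # interpolated path and never satisfy the dispersion criterion
  n <- length(t)
  x <- x + rnorm(n, 0, sh$noise_sd_px) * in_fix
  y <- y + rnorm(n, 0, sh$noise_sd_px) * in_fix
  gap <- !in_fix & !in_blink
  ng <- sum(gap)
  if (ng > 0) {
    r <- runif(ng, sh$gap_jitter_px, 1.8 * sh$gap_jitter_px)
    th <- runif(ng, 0, 2 * pi)
    x[gap] <- x[gap] + r * cos(th)
    y[gap] <- y[gap] + r * sin(th)
  }
  x <- pmin(pmax(x, 0), sh$frame_w_px - 1e-9)
  y <- pmin(pmax(y, 0), sh$frame_h_px - 1e-9)

  gaze_samples(t, x, y, valid = !in_blink)
}

#' Generate a full synthetic study
#'
#' Crossed within-subject design: every participant drives once rested and
#' once sleep-deprived. Between-subject heterogeneity enters as per-participant
#' multiplicative offsets (lognormal, clamped to \[0.55, 1.7\]) on fixation
#' rate, blink rate, blink/fixation duration and spatial scale, shared across
#' the participant's two sessions. Sessions get independent sub-seeds derived
#' from `seed`.
#'
#' @param params a [gaze_params()] object.
#' @param n_participants number of participants (default 9).
#' @param seed integer master seed.
#' @param emit_samples rasterise 50 Hz streams (default FALSE: a full study
#'   is 6.5 million samples; event ground truth is enough for the
#'   binning/statistics stages).
#' @param between_cv named numeric: coefficients of variation of the
#'   between-participant offsets.
#' @param session_cv lognormal sd of an additional per-session (day-to-day)
#'   jitter on the same quantities, independent across a participant's two
#'   sessions.
#' @return object of class `gaze_study`: a list of `gaze_session`s.
#' @export
generate_study <- function(params, n_participants = 9, seed = 1,
                           emit_samples = FALSE,
                           between_cv = c(rate = 0.15, blink = 0.25,
                                          duration = 0.10, spatial = 0.20),
                           session_cv = 0.08) {
  stopifnot(n_participants >= 1)
  withr::local_seed(as.integer(seed))
  offs <- tibble(
    participant = sprintf("P%02d", seq_len(n_participants)),
    rate = clamp_offset(rlnorm(n_participants, 0, between_cv[["rate"]])),
    blink = clamp_offset(rlnorm(n_participants, 0, between_cv[["blink"]])),
    duration = pmin(pmax(rlnorm(n_participants, 0, between_cv[["duration"]]),
                         0.8), 1.2),
    spatial = clamp_offset(rlnorm(n_participants, 0, between_cv[["spatial"]]))
  )
  sub_seeds <- sample.int(2^30, n_participants * 2)
  sessions <- vector("list", n_participants * 2)
  k <- 0
  for (i in seq_len(n_participants)) {
    for (cond in c("rested", "sleep_deprived")) {
      k <- k + 1
      day <- clamp_offset(rlnorm(4, 0, session_cv))
      sessions[[k]] <- generate_session(
        params, offs$participant[i], cond, seed = sub_seeds[k],
        emit_samples = emit_samples,
        rate_offset = offs$rate[i] * day[1],
        blink_offset = offs$blink[i] * day[2],
        duration_offset = offs$duration[i] * day[3],
        spatial_offset = offs$spatial[i] * day[4]
      )
    }
  }
  structure(list(sessions = sessions, offsets = offs, params = params,
                 seed = seed),
            class = "gaze_study")
}

clamp_offset <- function(x) pmin(pmax(x, 0.55), 1.7)

#' @export
print.gaze_study <- function(x, ...) {
  cat(sprintf("<gaze_study> %d sessions (%d participants x 2 conditions)\n",
              length(x$sessions), nrow(x$offsets)))
  invisible(x)
}

#' Collect study-level event tables from a synthetic study
#'
#' Either takes the generator's ground-truth events (`source = "truth"`) or
#' re-detects events from the rasterised sample streams
#' (`source = "detected"`, requires `emit_samples = TRUE` at generation).
#' Saccades are derived from consecutive fixations per session.
#'
#' @param study a `gaze_study` (or list of `gaze_session`s).
#' @param source `"truth"` or `"detected"`.
#' @param min_duration_ms,max_dispersion_px I-DT thresholds for
#'   `source = "detected"`.
#' @param deg_per_px degrees of visual angle per pixel for saccade amplitudes.
#' @return list: `records`, `fixations`, `saccades`, `blinks`
#'   (filtered at 300 ms), `lane`.
#' @export
study_event_tables <- function(study, source = c("truth", "detected"),
                               min_duration_ms = 80, max_dispersion_px = 100,
                               deg_per_px = 0.05) {
  source <- match.arg(source)
  sessions <- if (inherits(study, "gaze_study")) study$sessions else study
  per <- purrr::map(sessions, function(s) {
    if (source == "truth") {
      fx <- s$fixations
      bl <- s$blinks
    } else {
      if (is.null(s$samples)) {
        abort("source = 'detected' needs sessions generated with emit_samples = TRUE")
      }
      fx <- detect_fixations(s$samples, min_duration_ms, max_dispersion_px) |>
        mutate(participant = s$record$participant,
               condition = s$record$condition, .before = 1)
      bl <- detect_blinks(s$samples) |>
        mutate(participant = s$record$participant,
               condition = s$record$condition, .before = 1)
    }
    sc <- saccade_amplitudes(fx, deg_per_px) |>
      mutate(participant = s$record$participant,
             condition = s$record$condition, .before = 1)
    list(record = s$record, fixations = fx, saccades = sc,
         blinks = filter_blinks(bl), lane = s$lane)
  })
  list(
    records = purrr::map_dfr(per, "record"),
    fixations = purrr::map_dfr(per, "fixations"),
    saccades = purrr::map_dfr(per, "saccades"),
    blinks = purrr::map_dfr(per, "blinks"),
    lane = purrr::map_dfr(per, "lane")
  )
}

#' Fast simulator for logistic lane-departure recovery experiments
#'
#' Draws a per-minute design directly from the latent lane-departure
#' occurrence model, skipping sample-level generation: participants x two
#' conditions x driven minutes, per-minute entropy drawn from
#' condition-dependent normal distributions (percent scale, matching the
#' levels the full generator realises on the 30 px grid), and the binary
#' outcome from the logistic model in `coef`.
#'
#' @param n_participants participants (two sessions each).
#' @param coef named logistic coefficients
#'   (`intercept`, `condition`, `per_min`, `hs_pct`), log-odds scale;
#'   defaults from [gaze_params()].
#' @param hs_mean,hs_sd named (rested / sleep_deprived) entropy-percent
#'   distribution parameters.
#' @param hs_ref centring constant of the entropy term.
#' @param cap_min session cap; `hazard_per_block` and `min_drive_min` control
#'   sleep-deprived early termination as in the full generator.
#' @param hazard_per_block,min_drive_min early-termination controls.
#' @param seed integer seed.
#' @return per-minute tibble: `participant`, `condition`, `minute`,
#'   `driving_min`, `Hs_pct`, `lane_departure`.
#' @export
simulate_lane_minutes <- function(n_participants = 9,
                                  coef = gaze_params()$shared$lane_logistic,
                                  hs_mean = c(rested = 89.6,
                                              sleep_deprived = 96.7),
                                  hs_sd = c(rested = 1.7,
                                            sleep_deprived = 0.8),
                                  hs_ref = 90, cap_min = 120,
                                  hazard_per_block = 0.06,
                                  min_drive_min = 30, seed = 1) {
  withr::local_seed(as.integer(seed))
  purrr::map_dfr(seq_len(n_participants), function(i) {
    purrr::map_dfr(c("rested", "sleep_deprived"), function(cond) {
      term <- cap_min
      if (cond == "sleep_deprived" && hazard_per_block > 0) {
        blocks <- seq(min_drive_min / 5 + 1, cap_min / 5)
        hit <- which(runif(length(blocks)) < hazard_per_block)
        if (length(hit) > 0) term <- blocks[hit[1]] * 5
      }
      m <- seq_len(term)
      hs <- pmin(pmax(rnorm(term, hs_mean[[cond]], hs_sd[[cond]]), 0), 100)
      eta <- coef[["intercept"]] +
        coef[["condition"]] * (cond == "sleep_deprived") +
        coef[["per_min"]] * (m - 1) +
        coef[["hs_pct"]] * (hs - hs_ref)
      tibble(
        participant = sprintf("P%02d", i), condition = cond,
        minute = m, driving_min = m - 1, Hs_pct = hs,
        lane_departure = rbinom(term, 1, plogis(eta))
      )
    })
  })
}

#' Fast simulator for Poisson lane-departure count experiments
#'
#' Per-minute counts from a log-linear Poisson intensity with a known
#' condition rate ratio and (optionally) per-5-minute-block trends, for rate
#' model recovery experiments.
#'
#' @param minutes_per_condition driven minutes simulated per condition.
#' @param base_rate_per_min rested intensity (events/minute).
#' @param rate_ratio_condition sleep-deprived / rested intensity ratio.
#' @param rate_ratio_per_block named per-block multiplicative trends;
#'   ignored unless `include_trend = TRUE`.
#' @param include_trend apply the per-block trends.
#' @param seed integer seed.
#' @return tibble: `condition`, `minute`, `block`, `exposure_min`, `count`.
#' @export
simulate_lane_counts <- function(minutes_per_condition = 1080,
                                 base_rate_per_min = 0.15,
                                 rate_ratio_condition = 3.79,
                                 rate_ratio_per_block =
                                   c(rested = 0.98, sleep_deprived = 1.065),
                                 include_trend = FALSE, seed = 1) {
  withr::local_seed(as.integer(seed))
  purrr::map_dfr(c("rested", "sleep_deprived"), function(cond) {
    m <- seq_len(minutes_per_condition)
    # minutes beyond one session cap belong to further 120-minute sessions,
    # so the within-session block index cycles
    block <- ceiling(((m - 1) %% 120 + 1) / 5)
    lograte <- log(base_rate_per_min) +
      log(rate_ratio_condition) * (cond == "sleep_deprived")
    if (include_trend) {
      lograte <- lograte + log(rate_ratio_per_block[[cond]]) * (block - 1)
    }
    tibble(
      condition = cond, minute = m, block = block, exposure_min = 1,
      count = rpois(length(m), exp(lograte))
    )
  })
}
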