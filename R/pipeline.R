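#' Pipeline configuration
#'
#' Collects every tunable of the analysis pipeline in one serialisable
#' object: I-DT detection thresholds (80 ms / 100 px defaults), the 300 ms
#' blink filter, the coarse and fine entropy grids (100 px with 5-minute
#' bins; 30 px with 1-minute bins), frame extent, the pixel-to-degree factor,
#' the transition-entropy normalisation convention, and the seed.
#'
#' @param ... overrides of the defaults (see [pipeline_defaults()]).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- utils::modifyList(pipeline_defaults(), list(...))
  with(cfg, stopifnot(
    min_duration_ms > 0, max_dispersion_px > 0, blink_max_ms > 0,
    grid_coarse_px > 0, grid_fine_px > 0,
    bin_length_min > 0, minute_bin_min > 0,
    frame_w_px > 0, frame_h_px > 0, deg_per_px > 0
  ))
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @export
pipeline_defaults <- function() {
  list(
    min_duration_ms = 80,
    max_dispersion_px = 100,
    blink_max_ms = 300,
    grid_coarse_px = 100,
    grid_fine_px = 30,
    bin_length_min = 5,
    minute_bin_min = 1,
    frame_w_px = 1280,
    frame_h_px = 960,
    deg_per_px = 0.05,
    h_max = "observed",
    cap_min = 120,
    seed = 1
  )
}

#' Read / write a pipeline configuration (YAML)
#'
#' @param path file path.
#' @param config a [pipeline_config()].
#' @export
read_config_yaml <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname read_config_yaml
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Validate pipeline input files
#'
#' Schema checks for the pipeline's CSV inputs: required columns and types,
#' strictly increasing timestamps in gaze-sample files, and non-negative
#' lane-departure counts. Failures are collected in the report, never
#' raised.
#'
#' @param gaze_paths,lane_paths character vectors of file paths (either may
#'   be empty).
#' @return tibble report: `file`, `check`, `ok`, `detail` — one row per
#'   check; an all-`ok` report means the inputs are well-formed.
#' @export
validate_inputs <- function(gaze_paths = character(),
                            lane_paths = character()) {
  rows <- list()
  note <- function(file, check, ok, detail = "") {
    rows[[length(rows) + 1]] <<- tibble(
      file = file, check = check, ok = ok, detail = detail
    )
  }
  for (p in gaze_paths) {
    smp <- tryCatch(
      readr::read_csv(p, col_types = readr::cols(.default = readr::col_double()),
                      progress = FALSE),
      error = function(e) NULL
    )
    if (is.null(smp)) { note(p, "parse", FALSE, "unreadable CSV"); next }
    note(p, "parse", TRUE)
    miss <- setdiff(c("t_ms", "x_px", "y_px", "valid"), names(smp))
    note(p, "columns", length(miss) == 0,
         if (length(miss)) paste("missing:", paste(miss, collapse = ", ")) else "")
    if (length(miss) == 0) {
      mono <- nrow(smp) < 2 || all(diff(smp$t_ms) > 0)
      note(p, "monotone_timestamps", mono,
           if (!mono) "timestamps not strictly increasing" else "")
      vv <- all(smp$valid %in% c(0, 1))
      note(p, "valid_flag", vv, if (!vv) "valid must be 0/1" else "")
    }
  }
  for (p in lane_paths) {
    lane <- tryCatch(readr::read_csv(p, show_col_types = FALSE,
                                     progress = FALSE),
                     error = function(e) NULL)
    if (is.null(lane)) { note(p, "parse", FALSE, "unreadable CSV"); next }
    note(p, "parse", TRUE)
    miss <- setdiff(c("participant", "condition", "minute", "count"),
                    names(lane))
    note(p, "columns", length(miss) == 0,
         if (length(miss)) paste("missing:", paste(miss, collapse = ", ")) else "")
    if (length(miss) == 0) {
      nn <- all(lane$count >= 0)
      note(p, "nonnegative_counts", nn,
           if (!nn) "negative lane-departure count" else "")
    }
  }
  if (length(rows) == 0) {
    return(tibble(file = character(), check = character(),
                  ok = logical(), detail = character()))
  }
  bind_rows(rows)
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Executes the stages in order — event collection, entropy, 5-minute bin
#' table with LOCF imputation, 1-minute prediction table, condition
#' contrasts, lane-departure rate model, survival curve, the base and full
#' logistic prediction models with ROC evaluation — and writes every artifact
#' (CSV/JSON) plus a manifest recording the configuration and seed to
#' `out_dir`.
#'
#' @param study a `gaze_study` from [generate_study()].
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param source `"truth"` or `"detected"` event source
#'   (see [study_event_tables()]).
#' @return (invisibly) a list with the in-memory results: `events`,
#'   `bin_table`, `minutes`, `anova`, `rate_model`, `km`, `base_model`,
#'   `full_model`, `lr`, `roc_base`, `roc_full`, `manifest`.
#' @export
run_pipeline <- function(study, config = pipeline_config(),
                         out_dir = tempfile("gazepipe"),
                         source = c("truth", "detected")) {
  source <- match.arg(source)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  artifacts <- character()
  emit <- function(name) artifacts <<- c(artifacts, name)

  ev <- stage("events", study_event_tables(
    study, source = source,
    min_duration_ms = config$min_duration_ms,
    max_dispersion_px = config$max_dispersion_px,
    deg_per_px = config$deg_per_px
  ))
  write_lane_csv(ev$lane, file.path(out_dir, "lane_minutes.csv"))
  emit("lane_minutes.csv")

  grid_coarse <- state_grid(config$grid_coarse_px, config$frame_w_px,
                            config$frame_h_px)
  ent <- stage("entropy", {
    purrr::map_dfr(split(ev$fixations,
                         paste(ev$fixations$participant,
                               ev$fixations$condition)), function(fx) {
      rec <- ev$records |>
        filter(.data$participant == fx$participant[1],
               .data$condition == fx$condition[1])
      entropy_timeseries(
        fx, grid_coarse, bin_length_min = config$bin_length_min,
        session_length_min = rec$termination_min, h_max = config$h_max
      ) |>
        mutate(participant = fx$participant[1],
               condition = fx$condition[1], .before = 1)
    })
  })
  write_entropy_csv(ent, file.path(out_dir, "entropy_bins.csv"))
  emit("entropy_bins.csv")

  bins <- stage("bin_table", {
    oc <- ocular_bin_summaries(ev$records, ev$fixations, ev$saccades,
                               ev$blinks, config$bin_length_min)
    build_bin_table(ev$records, oc, ent, ev$lane,
                    bin_length_min = config$bin_length_min,
                    cap_min = config$cap_min) |>
      impute_locf()
  })
  readr::write_csv(
    bins |> mutate(imputed = as.integer(.data$imputed)),
    file.path(out_dir, "bin_table.csv")
  )
  emit("bin_table.csv")

  minutes <- stage("minute_table", minute_table(
    ev$records, ev$fixations, ev$saccades, ev$blinks, ev$lane,
    grid = state_grid(config$grid_fine_px, config$frame_w_px,
                      config$frame_h_px),
    h_max = config$h_max
  ))
  readr::write_csv(minutes, file.path(out_dir, "minute_table.csv"))
  emit("minute_table.csv")

  fits <- stage("fit", {
    anova_tbl <- purrr::map_dfr(
      c("blink_rate", "blink_duration_ms", "fixation_rate",
        "fixation_duration_ms", "saccade_amplitude_deg",
        "Hs_norm", "Ht_norm"),
      ~ rm_anova_condition(bins, .x)
    )
    session_counts <- ev$lane |>
      group_by(.data$participant, .data$condition) |>
      summarise(count = sum(.data$count),
                exposure_min = max(.data$minute), .groups = "drop")
    rate <- poisson_rate_model(session_counts, count ~ condition)
    km <- km_curve(ev$records)
    base <- logistic_lane_model(
      minutes, c("condition", "driving_min", "condition:driving_min")
    )
    full_rows <- stats::complete.cases(
      minutes[, c("condition", "driving_min", "blink_rate",
                  "blink_duration_ms", "fixation_rate",
                  "saccade_amplitude_deg", "Hs_pct", "Ht_pct")]
    )
    mfull <- minutes[full_rows, ]
    base_n <- logistic_lane_model(
      mfull, c("condition", "driving_min", "condition:driving_min")
    )
    full <- logistic_lane_model(
      mfull, c("condition", "driving_min", "condition:driving_min",
               "blink_rate", "blink_duration_ms", "fixation_rate",
               "saccade_amplitude_deg", "Hs_pct", "Ht_pct")
    )
    list(anova = anova_tbl, rate = rate, km = km, base = base,
         base_nested = base_n, full = full,
         lr = lr_test(base_n, full))
  })

  roc_base <- stage("roc", roc_evaluate(fits$base$prob, fits$base$outcome))
  roc_full <- stage("roc", roc_evaluate(fits$full$prob, fits$full$outcome))
  write_roc_csv(roc_base, file.path(out_dir, "roc_base.csv"))
  write_roc_csv(roc_full, file.path(out_dir, "roc_full.csv"))
  emit("roc_base.csv"); emit("roc_full.csv")

  model_json <- list(
    anova = fits$anova,
    rate_ratios = tidy(fits$rate),
    km = tidy(fits$km),
    base_model = tidy(fits$base),
    full_model = tidy(fits$full),
    lr_test = fits$lr,
    roc = bind_rows(
      glance(roc_base) |> mutate(model = "base", .before = 1),
      glance(roc_full) |> mutate(model = "full", .before = 1)
    )
  )
  jsonlite::write_json(model_json, file.path(out_dir, "models.json"),
                       dataframe = "rows", digits = NA, auto_unbox = TRUE)
  emit("models.json")

  manifest <- list(
    config = unclass(config),
    seed = if (inherits(study, "gaze_study")) study$seed else NA,
    source = source,
    n_sessions = length(if (inherits(study, "gaze_study")) study$sessions
                        else study),
    artifacts = artifacts,
    config_hash = rlang::hash(list(unclass(config),
                                   if (inherits(study, "gaze_study"))
                                     study$seed else NA))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(
    events = ev, entropy = ent, bin_table = bins, minutes = minutes,
    anova = fits$anova, rate_model = fits$rate, km = fits$km,
    base_model = fits$base, full_model = fits$full, lr = fits$lr,
    roc_base = roc_base, roc_full = roc_full, manifest = manifest,
    out_dir = out_dir
  ))
}
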