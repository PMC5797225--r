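#' Plot an entropy (or any measure) time course by condition
#'
#' Mean and standard-error ribbon of a per-bin measure across driving time,
#' one colour per condition — the conventional display of time-on-task
#' effects.
#'
#' @param bin_table per-bin table (post-imputation for balanced panels).
#' @param measure column name (string), e.g. `"Hs_norm"` or `"blink_rate"`.
#' @return a ggplot object.
#' @export
plot_timecourse <- function(bin_table, measure = "Hs_norm") {
  dat <- bin_table |>
    group_by(.data$condition, .data$bin_start_min) |>
    summarise(
      m = mean(.data[[measure]], na.rm = TRUE),
      se = sd(.data[[measure]], na.rm = TRUE) /
        sqrt(sum(!is.na(.data[[measure]]))),
      .groups = "drop"
    )
  ggplot2::ggplot(dat, ggplot2::aes(.data$bin_start_min, .data$m,
                                    colour = .data$condition,
                                    fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$m - .data$se,
                                      ymax = .data$m + .data$se),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "driving time (min)", y = measure) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gaze_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::annotate("point", x = 1 - object$specificity,
                      y = object$sensitivity, colour = "red") +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("ROC (AUC = %.2f)", object$auc)
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gaze_km <- function(object, ...) {
  steps <- tidy(object) |>
    group_by(.data$condition) |>
    group_modify(~ bind_rows(
      tibble(time = 0, survival = 1), .x[, c("time", "survival")]
    )) |>
    ungroup()
  ggplot2::ggplot(steps, ggplot2::aes(.data$time, .data$survival,
                                      colour = .data$condition)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "driving time (min)",
                  y = "probability of continuing to drive") +
    ggplot2::theme_minimal()
}

#' Fixation density plot
#'
#' 2D density of fixation centroids over the scene frame, facetted by
#' condition: rested gaze concentrates on the road-ahead region while
#' sleep-deprived gaze disperses.
#'
#' @param fixations study fixation table with `condition`, `cx_px`, `cy_px`.
#' @return a ggplot object.
#' @export
plot_fixation_density <- function(fixations) {
  ggplot2::ggplot(fixations, ggplot2::aes(.data$cx_px, .data$cy_px)) +
    ggplot2::geom_bin2d(binwidth = c(50, 50)) +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
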