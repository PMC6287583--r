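#' Fixation map of endpoint errors
#'
#' Scatter of signed endpoint errors around each target (canonical frame),
#' faceted by target and condition, in the style of a fixation-map figure:
#' zero error is the target, negative first-target errors are hypometric.
#'
#' @param observations Output of [preprocess_trials()].
#' @param subjects Optional subject table supplying a `group` colour.
#' @return A ggplot object.
#' @export
plot_fixation_map <- function(observations, subjects = NULL) {
  err <- errors_long(observations, subjects)
  if (!"group" %in% names(err)) err$group <- "all"
  ggplot2::ggplot(err, ggplot2::aes(x = .data$dx, y = .data$dy,
                                    colour = .data$group)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::facet_grid(condition ~ target) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "horizontal error (px)", y = "vertical error (px)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.saccade_cohort <- function(object, ...) {
  plot_fixation_map(preprocess_trials(object$fixations), object$subjects)
}

#' Compensation scatter: actual vs ideal second-saccade angle
#'
#' Executed second-saccade angle against the centred ideal angle with group
#' regression lines per condition; a unit slope is complete trial-by-trial
#' compensation for first-saccade scatter.
#'
#' @param records Output of [compensation_records()] +
#'   [center_predictors()].
#' @param response `"angle"` or `"amp"`.
#' @return A ggplot object.
#' @export
plot_compensation <- function(records, response = c("angle", "amp")) {
  response <- match.arg(response)
  xvar <- paste0("centered_ideal_", response)
  yvar <- paste0("actual_", response)
  if (!xvar %in% names(records)) records <- center_predictors(records)
  if (!"group" %in% names(records)) records$group <- "all"
  ggplot2::ggplot(records, ggplot2::aes(x = .data[[xvar]], y = .data[[yvar]],
                                        colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.7) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(
      x = paste("centred ideal", response),
      y = paste("actual second-saccade", response),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Threshold boxplot by condition
#'
#' @param results Threshold results (e.g. [simulate_threshold_study()]).
#' @return A ggplot object.
#' @export
plot_thresholds <- function(results) {
  results <- dplyr::mutate(
    results,
    condition = factor(.data$condition,
                       levels = c("fixation", "saccade", "after_saccade"))
  )
  ggplot2::ggplot(results, ggplot2::aes(x = .data$condition,
                                        y = .data$log10_threshold)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "log10 Michelson contrast threshold") +
    ggplot2::theme_minimal()
}

#' Coefficient (forest) plot of a fitted model
#'
#' @param object A `saccade_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.saccade_model <- function(object, ...) {
  tab <- dplyr::filter(tidy(object), .data$term != "(Intercept)")
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "estimate (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
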