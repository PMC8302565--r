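#' Plot Levelt-II condition curves
#'
#' Mean dominance duration or dominance proportion per percept as a
#' function of the intensity difference, with SEM error bars. The
#' proportion panel carries a dashed equidominance line at 0.5.
#'
#' @param object A [condition_curves()] result.
#' @param metric `"duration"` or `"proportion"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rivalry_curves <- function(object, metric = c("duration", "proportion"),
                                    ...) {
  metric <- match.arg(metric)
  if (metric == "duration") {
    p <- ggplot(object, aes(delta_i_db, mean_duration_s, colour = percept)) +
      geom_errorbar(aes(ymin = mean_duration_s - se_duration,
                        ymax = mean_duration_s + se_duration), width = 0.1) +
      labs(y = "mean dominance duration (s)")
  } else {
    p <- ggplot(object, aes(delta_i_db, mean_prop, colour = percept)) +
      geom_errorbar(aes(ymin = mean_prop - se_prop,
                        ymax = mean_prop + se_prop), width = 0.1) +
      geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey50") +
      labs(y = "proportion of dominance")
  }
  p + geom_line() + geom_point() +
    labs(x = expression(Delta * I ~ "(dB)")) +
    theme_minimal()
}

#' @rdname autoplot.rivalry_curves
#' @param curves A [condition_curves()] result.
#' @export
plot_condition_curves <- function(curves, metric = c("duration", "proportion")) {
  autoplot(curves, metric = metric)
}

#' Plot the alternation-rate curve
#'
#' @param rate_curve An [alternation_rate_curve()] result.
#' @return A ggplot of mean switches per minute against dB with SEM bars.
#' @export
plot_alternation_rate <- function(rate_curve) {
  ggplot(rate_curve, aes(delta_i_db, mean_rate)) +
    geom_errorbar(aes(ymin = mean_rate - se_rate, ymax = mean_rate + se_rate),
                  width = 0.1) +
    geom_line() + geom_point() +
    labs(x = expression(Delta * I ~ "(dB)"),
         y = "alternation rate (switches/min)") +
    theme_minimal()
}

#' Histogram of durations with the fitted density
#'
#' @param object A [fit_duration_dist()] result (which keeps its sample).
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot of the sample histogram with the fitted gamma or
#'   log-normal density overlaid.
#' @export
autoplot.duration_fit <- function(object, bins = 30, ...) {
  grid <- seq(min(object$x), max(object$x), length.out = 256)
  dens <- tibble(x = grid, density = fit_pdf(object)(grid))
  ggplot(tibble(x = object$x), aes(x)) +
    geom_histogram(aes(y = after_stat(density)), bins = bins,
                   fill = "grey80", colour = "grey40") +
    geom_line(data = dens, aes(x, density), colour = "firebrick") +
    labs(x = "duration", y = "density",
         title = paste0(object$family, " fit (n = ", object$n, ")")) +
    theme_minimal()
}

#' @rdname autoplot.duration_fit
#' @param fit A [fit_duration_dist()] result.
#' @export
plot_duration_fit <- function(fit, bins = 30) autoplot(fit, bins = bins)

#' Scatter plot of lagged duration pairs
#'
#' @param pairs A [lagged_pairs()] result.
#' @param transition Optional label for the title.
#' @return A ggplot of each phase's duration against the lagged one.
#' @export
plot_lag_scatter <- function(pairs, transition = NULL) {
  ggplot(pairs, aes(first_dur, second_dur)) +
    geom_point(alpha = 0.4, size = 0.8) +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                colour = "firebrick", linewidth = 0.6) +
    labs(x = "duration", y = "lagged duration", title = transition) +
    theme_minimal()
}

#' Normalized moments per condition with bootstrap intervals
#'
#' @param object A [scaling_assessment()] result.
#' @param ... Unused.
#' @return A ggplot of cv and gamma1/cv against dB; flat curves within
#'   their intervals express the scaling property.
#' @export
autoplot.scaling_assessment <- function(object, ...) {
  long <- dplyr::bind_rows(
    object$by_condition |>
      dplyr::transmute(delta_i_db, metric = "cv", value = cv,
                       lo = .data$cv_lo, hi = .data$cv_hi),
    object$by_condition |>
      dplyr::transmute(delta_i_db, metric = "gamma1/cv",
                       value = gamma1_over_cv,
                       lo = .data$g1cv_lo, hi = .data$g1cv_hi)
  )
  ggplot(long, aes(delta_i_db, value)) +
    geom_errorbar(aes(ymin = lo, ymax = hi), width = 0.1) +
    geom_line() + geom_point() +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = expression(Delta * I ~ "(dB)"), y = NULL) +
    theme_minimal()
}
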