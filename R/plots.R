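axis_label <- function(axis) {
  switch(axis,
    n_individuals = "Number of individuals",
    n_calls = "Calls per individual",
    axis
  )
}

#' Plot a resampling sweep
#'
#' Mean accuracy with a 95% normal confidence band over repetitions, at both
#' the call and the individual level.
#'
#' @param object A `sweep_result` from [sweep_population_size()] or
#'   [sweep_calls_per_individual()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sweep_result
#' @export
autoplot.sweep_result <- function(object, ...) {
  long <- object |>
    pivot_longer(
      c("call_accuracy", "individual_accuracy"),
      names_to = "level", values_to = "accuracy"
    ) |>
    mutate(level = ifelse(.data$level == "call_accuracy", "call", "individual")) |>
    group_by(.data$step, .data$level) |>
    summarise(
      mean = mean(.data$accuracy),
      se = sd(.data$accuracy) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot(long, aes(x = .data$step, y = .data$mean, colour = .data$level, fill = .data$level)) +
    geom_ribbon(
      aes(ymin = pmax(.data$mean - 1.96 * .data$se, 0), ymax = pmin(.data$mean + 1.96 * .data$se, 1)),
      alpha = 0.2, colour = NA
    ) +
    geom_line() +
    scale_y_continuous(limits = c(0, 1), labels = function(x) sprintf("%.0f%%", 100 * x)) +
    labs(
      x = axis_label(attr(object, "axis")),
      y = "Discrimination accuracy",
      colour = "Level", fill = "Level"
    ) +
    theme_minimal()
}

#' Plot an identity-information curve
#'
#' Mean Beecher's H_S against the number of individuals sampled.
#'
#' @param object An `hs_curve` from [hs_population_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hs_curve
#' @export
autoplot.hs_curve <- function(object, ...) {
  means <- object |>
    group_by(.data$size) |>
    summarise(mean_hs = mean(.data$hs), .groups = "drop")
  ggplot(means, aes(x = .data$size, y = .data$mean_hs)) +
    geom_line() +
    geom_point(size = 0.8) +
    labs(x = "Number of individuals", y = expression(H[S] ~ "(bits)")) +
    theme_minimal()
}

#' Plot a confusion matrix
#'
#' @param object A [confusion_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot confusion_matrix
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$predicted, y = .data$true, fill = .data$count)) +
    geom_tile() +
    geom_text(aes(label = .data$count), size = 3) +
    scale_fill_gradient(low = "white", high = "steelblue") +
    scale_y_discrete(limits = rev) +
    labs(x = "Assigned individual", y = "True individual", fill = "Calls") +
    theme_minimal()
}

#' Plot pilot-predicted vs realized discriminable individuals
#'
#' Scatter of the realized number of discriminated individuals against the
#' number predicted from the pilot H_S, with the ideal `y = x` line.
#'
#' @param object A `prescreen_result` from [prescreen_models()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot prescreen_result
#' @export
autoplot.prescreen_result <- function(object, ...) {
  ggplot(object, aes(x = .data$n_estimated, y = .data$n_realized)) +
    geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    geom_point() +
    labs(
      x = "Individuals predicted discriminable (pilot)",
      y = "Individuals discriminated (full set)"
    ) +
    theme_minimal()
}
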