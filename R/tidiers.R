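#' Tidy the per-component table of an H_S result
#'
#' @param x An `hs_result` from [compute_hs()].
#' @param ... Unused.
#' @return A tibble with one row per principal component: `component`,
#'   `sdev`, `F` (one-way ANOVA F), `h` (identity information in bits).
#' @method tidy hs_result
#' @export
tidy.hs_result <- function(x, ...) {
  x$components
}

#' One-row summary of an H_S result
#'
#' @param x An `hs_result`.
#' @param ... Unused.
#' @return A one-row tibble: `hs`, `n_individuals`, `n_calls`,
#'   `n_components`.
#' @method glance hs_result
#' @export
glance.hs_result <- function(x, ...) {
  tibble(
    hs = x$hs,
    n_individuals = x$n,
    n_calls = x$n_calls,
    n_components = nrow(x$components)
  )
}

#' Long-format confusion matrix
#'
#' @param x A [confusion_matrix()].
#' @param ... Unused.
#' @return A tibble with `true`, `predicted`, `count`.
#' @method tidy confusion_matrix
#' @export
tidy.confusion_matrix <- function(x, ...) {
  df <- as.data.frame.table(unclass(x), responseName = "count", stringsAsFactors = FALSE)
  as_tibble(setNames(df, c("true", "predicted", "count")))
}

#' One-row summary of an assignment result
#'
#' Equivalent to [discrimination_summary()].
#'
#' @param x An `assignment_result`.
#' @param ... Unused.
#' @return A one-row tibble with both accuracy levels, sizes and tie count.
#' @method glance assignment_result
#' @export
glance.assignment_result <- function(x, ...) {
  discrimination_summary(x)
}

#' Per-step summary of a sweep
#'
#' @param x A `sweep_result`.
#' @param ... Unused.
#' @return A tibble with one row per step: mean and standard error of both
#'   accuracy levels over repetitions.
#' @method tidy sweep_result
#' @export
tidy.sweep_result <- function(x, ...) {
  x |>
    group_by(.data$axis, .data$step) |>
    summarise(
      mean_call_accuracy = mean(.data$call_accuracy),
      se_call_accuracy = sd(.data$call_accuracy) / sqrt(dplyr::n()),
      mean_individual_accuracy = mean(.data$individual_accuracy),
      se_individual_accuracy = sd(.data$individual_accuracy) / sqrt(dplyr::n()),
      n_reps = dplyr::n(),
      .groups = "drop"
    )
}
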