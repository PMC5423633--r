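#' Pre-screen candidate feature sets with a pilot subsample
#'
#' Emulates the pre-screening workflow of an acoustic-monitoring pilot
#' study: for each candidate feature set, compute the identity information
#' H_S on small random subsets of individuals (the pilot), compute H_S and
#' the full leave-one-out LDA performance on the complete dataset, and
#' convert the pilot H_S into a predicted number of discriminable
#' individuals via `N = P * 2^H_S`. Comparing the prediction with the
#' number of individuals actually discriminated shows how far a pilot study
#' can be trusted.
#'
#' The same random subsets are used for every feature set so that models
#' are compared on identical pilots.
#'
#' @param data A call dataset.
#' @param specs List of feature sets: [feature_spec()] objects or character
#'   vectors (see [measuring_point_specs()] for a ready-made family).
#' @param subset_size Individuals per pilot subset (default 10; may equal
#'   the total number of individuals, in which case the pilot H_S equals the
#'   full H_S).
#' @param n_reps Number of random pilot subsets averaged. Default 20.
#' @param P Signature-uniqueness probability for
#'   [estimate_discriminable_n()]. Default 0.9.
#' @param seed Integer seed.
#' @return A `prescreen_result` tibble, one row per feature set: `model`,
#'   `hs_subset` (mean pilot H_S), `hs_full`, `call_accuracy`,
#'   `individual_accuracy`, `n_estimated` (from the pilot H_S),
#'   `n_realized` (`round(individual_accuracy * n_individuals)`).
#' @export
prescreen_models <- function(data, specs, subset_size = 10, n_reps = 20,
                             P = 0.9, seed = 1L) {
  data <- call_dataset(data)
  check_discrimination_ready(data)
  if (!is.list(specs) || length(specs) == 0L) {
    abort("`specs` must be a non-empty list of feature specs", class = "vocalid_parameter_error")
  }
  inds <- sort(unique(data$individual))
  subset_size <- as.integer(subset_size)
  if (subset_size < 2L || subset_size > length(inds)) {
    abort(
      sprintf("subset_size must lie in [2, %d]", length(inds)),
      class = "vocalid_parameter_error"
    )
  }
  set.seed(as.integer(seed))
  subsets <- lapply(seq_len(n_reps), function(r) sample(inds, subset_size))

  names(specs) <- names(specs) %||% rep("", length(specs))
  rows <- imap(specs, function(sp, nm) {
    model <- if (nzchar(nm)) nm else spec_name(sp)
    hs_full <- compute_hs(data, sp)$hs
    hs_subset <- mean(map_dbl(subsets, function(s) {
      compute_hs(data[data$individual %in% s, , drop = FALSE], sp)$hs
    }))
    summ <- discrimination_summary(classify_loo_lda(data, sp))
    tibble(
      model = model,
      hs_subset = hs_subset,
      hs_full = hs_full,
      call_accuracy = summ$call_accuracy,
      individual_accuracy = summ$individual_accuracy,
      n_estimated = estimate_discriminable_n(hs_subset, P)$n,
      n_realized = as.integer(round(summ$individual_accuracy * length(inds)))
    )
  })
  out <- bind_rows(rows)
  attr(out, "subset_size") <- subset_size
  attr(out, "n_reps") <- n_reps
  attr(out, "P") <- P
  attr(out, "seed") <- as.integer(seed)
  class(out) <- unique(c("prescreen_result", class(out)))
  out
}

#' Association between pilot predictions and realized discrimination
#'
#' Summarises how well the pilot pre-screening of [prescreen_models()]
#' anticipates full-population performance: Spearman rank correlations of
#' the pilot H_S with the full-set H_S and with the full-set call accuracy,
#' and an ordinary least-squares regression (with intercept) of the
#' realized number of discriminated individuals on the pilot-predicted
#' number.
#'
#' @param records A `prescreen_result` (or data frame with columns
#'   `hs_subset`, `hs_full`, `call_accuracy`, `n_estimated`, `n_realized`);
#'   at least 3 rows.
#' @return A one-row tibble: `spearman_hs`, `spearman_accuracy`,
#'   `intercept`, `slope`, `f_statistic`, `df1`, `df2`, `adj_r_squared`,
#'   `p_value`. Correlations on constant vectors are undefined and reported
#'   as `NA` with a warning.
#' @export
correlate_prescreen <- function(records) {
  needed <- c("hs_subset", "hs_full", "call_accuracy", "n_estimated", "n_realized")
  if (!is.data.frame(records) || !all(needed %in% names(records))) {
    abort("`records` must be a prescreen result", class = "vocalid_parameter_error")
  }
  if (nrow(records) < 3L) {
    abort("need at least 3 models to correlate", class = "vocalid_parameter_error")
  }
  spearman <- function(x, y) {
    if (sd(x) == 0 || sd(y) == 0) {
      warn("constant vector: Spearman correlation undefined", class = "vocalid_degenerate_warning")
      return(NA_real_)
    }
    cor(x, y, method = "spearman")
  }
  sp_hs <- spearman(records$hs_subset, records$hs_full)
  sp_acc <- spearman(records$hs_subset, records$call_accuracy)

  if (sd(records$n_estimated) == 0) {
    warn("constant predictor: regression undefined", class = "vocalid_degenerate_warning")
    reg <- tibble(
      intercept = NA_real_, slope = NA_real_, f_statistic = NA_real_,
      df1 = NA_real_, df2 = NA_real_, adj_r_squared = NA_real_, p_value = NA_real_
    )
  } else {
    fit <- lm(n_realized ~ n_estimated, data = records)
    s <- suppressWarnings(summary(fit))
    fs <- s$fstatistic
    reg <- tibble(
      intercept = unname(coef(fit)[1]),
      slope = unname(coef(fit)[2]),
      f_statistic = unname(fs[1]),
      df1 = unname(fs[2]),
      df2 = unname(fs[3]),
      adj_r_squared = s$adj.r.squared,
      p_value = unname(pf(fs[1], fs[2], fs[3], lower.tail = FALSE))
    )
  }
  dplyr::bind_cols(tibble(spearman_hs = sp_hs, spearman_accuracy = sp_acc), reg)
}
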