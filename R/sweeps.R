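# Shared evaluation kernel of the resampling experiments: classify a subset
# of individuals (and optionally a subset of calls) and summarise it.
eval_subset <- function(method, data, similarity, features, inds, calls_keep = NULL) {
  if (method == "lda") {
    d <- data[data$individual %in% inds, , drop = FALSE]
    if (!is.null(calls_keep)) d <- d[d$call %in% calls_keep, , drop = FALSE]
    res <- classify_loo_lda(d, features)
  } else {
    sm <- sm_subset(similarity, individuals = inds, calls = calls_keep)
    res <- classify_similarity(sm)
  }
  discrimination_summary(res)
}

with_step_context <- function(expr, rep, step, axis) {
  tryCatch(expr, error = function(e) {
    abort(
      sprintf("classifier failed at %s = %d (repetition %d)", axis, step, rep),
      parent = e
    )
  })
}

sweep_individuals <- function(method, data, similarity) {
  if (method == "lda") {
    if (is.null(data)) abort("`data` is required for method = \"lda\"", class = "vocalid_parameter_error")
    data <- call_dataset(data)
    sort(unique(data$individual))
  } else {
    if (is.null(similarity)) abort("`similarity` is required for method = \"similarity\"", class = "vocalid_parameter_error")
    sort(unique(similarity$individuals))
  }
}

new_sweep_result <- function(rows, axis, method, features, n_reps, seed) {
  out <- rows
  attr(out, "axis") <- axis
  attr(out, "method") <- method
  attr(out, "features") <- features
  attr(out, "n_reps") <- n_reps
  attr(out, "seed") <- seed
  class(out) <- unique(c("sweep_result", class(out)))
  out
}

#' Discrimination performance as a function of population size
#'
#' Resampling experiment: in each repetition a random ordering of the
#' individuals is drawn and the classifier is evaluated on nested growing
#' subsets — starting from the first `sizes[1]` individuals and adding one
#' randomly chosen individual at a time (the incremental design). Call- and
#' individual-level accuracies are recorded at every step. Averaging the
#' repetitions exposes the bias of quoting discrimination performance
#' without the population size it was measured at.
#'
#' @param data A call dataset (required for `method = "lda"`).
#' @param method `"lda"` (leave-one-out LDA on features) or `"similarity"`
#'   (average-similarity rule on a score matrix).
#' @param sizes Population sizes to evaluate; default `2:n_individuals`.
#' @param n_reps Number of random individual orderings. Default 20.
#' @param seed Integer seed; all randomness of the sweep derives from it.
#' @param features Feature selection for the LDA method.
#' @param similarity A [similarity_matrix()] (required for
#'   `method = "similarity"`).
#' @return A `sweep_result` tibble: one row per step x repetition with
#'   `axis`, `step`, `rep`, `call_accuracy`, `individual_accuracy`, `ties`.
#' @examples
#' calls <- generate_population(n_individuals = 6, calls_per_individual = 5, seed = 3)
#' sweep_population_size(calls, sizes = c(2, 4, 6), n_reps = 3, seed = 1)
#' @export
sweep_population_size <- function(data = NULL, method = c("lda", "similarity"),
                                  sizes = NULL, n_reps = 20, seed = 1L,
                                  features = NULL, similarity = NULL) {
  method <- match.arg(method)
  inds <- sweep_individuals(method, data, similarity)
  if (method == "lda") data <- call_dataset(data)
  sizes <- sort(unique(as.integer(sizes %||% seq(2L, length(inds)))))
  if (min(sizes) < 2L || max(sizes) > length(inds)) {
    abort(
      sprintf("sizes must lie in [2, %d]", length(inds)),
      class = "vocalid_parameter_error"
    )
  }
  set.seed(as.integer(seed))
  orders <- lapply(seq_len(n_reps), function(r) sample(inds))
  rows <- map_dfr(seq_len(n_reps), function(r) {
    map_dfr(sizes, function(s) {
      summ <- with_step_context(
        eval_subset(method, data, similarity, features, orders[[r]][seq_len(s)]),
        r, s, "n_individuals"
      )
      dplyr::bind_cols(tibble(axis = "n_individuals", step = s, rep = r), summ)
    })
  })
  new_sweep_result(rows, "n_individuals", method, spec_name(features), n_reps, seed)
}

#' Discrimination performance as a function of calls per individual
#'
#' In each repetition and at each step `k`, `k` calls are subsampled per
#' individual without replacement and the classifier is evaluated on that
#' reduced dataset. Individuals with fewer than `max(calls)` calls are
#' excluded with a warning so every step uses the same individuals.
#' Increasing the number of calls per individual barely changes call-level
#' accuracy once the discriminant is stable, but keeps improving
#' individual-level accuracy: more calls per bout make the plurality rule
#' more forgiving of individually similar callers.
#'
#' @inheritParams sweep_population_size
#' @param calls Steps of calls-per-individual; each must be >= 2
#'   (leave-one-out is undefined at 1). Default `2:20`.
#' @return A `sweep_result` tibble with `axis = "n_calls"`.
#' @export
sweep_calls_per_individual <- function(data = NULL, method = c("lda", "similarity"),
                                       calls = 2:20, n_reps = 20, seed = 1L,
                                       features = NULL, similarity = NULL) {
  method <- match.arg(method)
  inds <- sweep_individuals(method, data, similarity)
  if (method == "lda") data <- call_dataset(data)
  calls <- sort(unique(as.integer(calls)))
  if (min(calls) < 2L) {
    abort("calls-per-individual steps must be >= 2", class = "vocalid_parameter_error")
  }
  call_ids <- if (method == "lda") {
    split(data$call, data$individual)
  } else {
    split(colnames(similarity$scores), similarity$individuals)
  }
  counts <- lengths(call_ids)
  short <- names(counts[counts < max(calls)])
  if (length(short)) {
    warn(
      sprintf(
        "excluding individual(s) with fewer than %d calls: %s",
        max(calls), paste(short, collapse = ", ")
      ),
      class = "vocalid_validation_warning"
    )
    inds <- setdiff(inds, short)
    call_ids <- call_ids[inds]
  }
  if (length(inds) < 2L) {
    abort("fewer than 2 individuals have enough calls", class = "vocalid_validation_error")
  }
  set.seed(as.integer(seed))
  rows <- map_dfr(seq_len(n_reps), function(r) {
    map_dfr(calls, function(k) {
      keep <- unlist(lapply(call_ids, function(ids) sample(ids, k)), use.names = FALSE)
      summ <- with_step_context(
        eval_subset(method, data, similarity, features, inds, keep),
        r, k, "n_calls"
      )
      dplyr::bind_cols(tibble(axis = "n_calls", step = k, rep = r), summ)
    })
  })
  new_sweep_result(rows, "n_calls", method, spec_name(features), n_reps, seed)
}

#' Largest population monitorable at a target reliability
#'
#' Runs a population-size sweep at a fixed number of calls per individual
#' and returns the largest population size whose mean accuracy (over
#' repetitions) still meets the criterion: at least 90% of individuals
#' correctly attributed (`criterion = "individual"`, the colour-ring
#' standard) or at least 65% of calls correctly assigned
#' (`criterion = "call"`). Within each repetition the subsets are nested and
#' the per-individual call subsample is drawn once.
#'
#' @inheritParams sweep_population_size
#' @param n_calls Calls subsampled per individual (>= 2). Individuals with
#'   fewer calls are excluded with a warning.
#' @param criterion `"individual"` or `"call"`.
#' @param threshold Accuracy threshold; defaults to 0.90 for the individual
#'   criterion and 0.65 for the call criterion.
#' @param sizes Population sizes to scan; default `2:n_individuals`.
#' @return A one-row tibble: `n_monitorable` (0 when the criterion fails
#'   already at the smallest size), `open_ended` (`TRUE` when the criterion
#'   holds up to the dataset maximum, i.e. the search never hit the limit),
#'   `criterion`, `threshold`, `n_calls`, `n_reps`, `seed`. The underlying
#'   per-size sweep is attached as `attr(, "sweep")`.
#' @export
monitorable_population <- function(data = NULL, method = c("lda", "similarity"),
                                   n_calls = 2, criterion = c("individual", "call"),
                                   threshold = NULL, n_reps = 20, seed = 1L,
                                   sizes = NULL, features = NULL, similarity = NULL) {
  method <- match.arg(method)
  criterion <- match.arg(criterion)
  threshold <- threshold %||% if (criterion == "individual") 0.90 else 0.65
  n_calls <- as.integer(n_calls)
  if (n_calls < 2L) abort("n_calls must be >= 2", class = "vocalid_parameter_error")
  inds <- sweep_individuals(method, data, similarity)
  if (method == "lda") data <- call_dataset(data)
  call_ids <- if (method == "lda") {
    split(data$call, data$individual)
  } else {
    split(colnames(similarity$scores), similarity$individuals)
  }
  counts <- lengths(call_ids)
  short <- names(counts[counts < n_calls])
  if (length(short)) {
    warn(
      sprintf(
        "excluding individual(s) with fewer than %d calls: %s",
        n_calls, paste(short, collapse = ", ")
      ),
      class = "vocalid_validation_warning"
    )
    inds <- setdiff(inds, short)
    call_ids <- call_ids[inds]
  }
  sizes <- sort(unique(as.integer(sizes %||% seq(2L, length(inds)))))
  if (min(sizes) < 2L || max(sizes) > length(inds)) {
    abort(sprintf("sizes must lie in [2, %d]", length(inds)), class = "vocalid_parameter_error")
  }

  set.seed(as.integer(seed))
  rows <- map_dfr(seq_len(n_reps), function(r) {
    ord <- sample(inds)
    keep <- unlist(lapply(call_ids, function(ids) sample(ids, n_calls)), use.names = FALSE)
    map_dfr(sizes, function(s) {
      summ <- with_step_context(
        eval_subset(method, data, similarity, features, ord[seq_len(s)], keep),
        r, s, "n_individuals"
      )
      dplyr::bind_cols(tibble(axis = "n_individuals", step = s, rep = r), summ)
    })
  })
  sweep <- new_sweep_result(rows, "n_individuals", method, spec_name(features), n_reps, seed)

  acc_col <- if (criterion == "individual") "individual_accuracy" else "call_accuracy"
  means <- rows |>
    group_by(.data$step) |>
    summarise(mean_accuracy = mean(.data[[acc_col]]), .groups = "drop")
  meets <- means$mean_accuracy >= threshold
  out <- tibble(
    n_monitorable = if (any(meets)) max(means$step[meets]) else 0L,
    open_ended = all(meets),
    criterion = criterion,
    threshold = threshold,
    n_calls = n_calls,
    n_reps = n_reps,
    seed = as.integer(seed)
  )
  attr(out, "sweep") <- sweep
  out
}

#' Identity information as a function of population size
#'
#' Computes Beecher's H_S on nested random subsets of individuals of
#' increasing size, repeated over random orderings. H_S is not
#' sample-size-free in practice: it typically rises steeply for the first
#' few individuals and then declines as more are added, which is the core
#' caveat for comparing H_S across studies.
#'
#' @inheritParams sweep_population_size
#' @param data A call dataset.
#' @return An `hs_curve` tibble: one row per size x repetition with
#'   `size`, `rep`, `hs`.
#' @export
hs_population_curve <- function(data, features = NULL, sizes = NULL,
                                n_reps = 20, seed = 1L) {
  data <- call_dataset(data)
  inds <- sort(unique(data$individual))
  sizes <- sort(unique(as.integer(sizes %||% seq(2L, length(inds)))))
  if (min(sizes) < 2L || max(sizes) > length(inds)) {
    abort(sprintf("sizes must lie in [2, %d]", length(inds)), class = "vocalid_parameter_error")
  }
  set.seed(as.integer(seed))
  orders <- lapply(seq_len(n_reps), function(r) sample(inds))
  rows <- map_dfr(seq_len(n_reps), function(r) {
    map_dfr(sizes, function(s) {
      hs <- with_step_context(
        compute_hs(data[data$individual %in% orders[[r]][seq_len(s)], , drop = FALSE], features)$hs,
        r, s, "n_individuals"
      )
      tibble(size = s, rep = r, hs = hs)
    })
  })
  attr(rows, "features") <- spec_name(features)
  attr(rows, "n_reps") <- n_reps
  attr(rows, "seed") <- seed
  class(rows) <- unique(c("hs_curve", class(rows)))
  rows
}
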