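# Deterministic argmax over score columns: lexicographically smallest
# individual label wins ties; ties are flagged per call.
argmax_lex <- function(scores) {
  scores <- scores[, order(colnames(scores)), drop = FALSE]
  rowmax <- do.call(pmax, as.data.frame(scores))
  tol <- 1e-12 * pmax(abs(rowmax), 1)
  is_max <- scores >= rowmax - tol
  first <- max.col(is_max, ties.method = "first")
  list(
    predicted = colnames(scores)[first],
    tie = rowSums(is_max) > 1L
  )
}

new_assignment_result <- function(call, individual, predicted, tie,
                                  classifier, features) {
  out <- tibble(
    call = call,
    individual = individual,
    predicted = predicted,
    correct = individual == predicted,
    tie = tie
  )
  attr(out, "classifier") <- classifier
  attr(out, "features") <- features
  class(out) <- unique(c("assignment_result", class(out)))
  out
}

# Leave-one-out LDA with an explicit pooled covariance; used only when
# MASS::lda rejects the input as singular. Ridge eps = 1e-8 * trace/dim is
# added to the pooled covariance diagonal only when it cannot be inverted.
loo_lda_scores <- function(X, g) {
  n <- nrow(X)
  labs <- levels(g)
  k <- length(labs)
  p <- ncol(X)
  out <- matrix(NA_real_, n, k, dimnames = list(NULL, labs))
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    gtr <- g[-i]
    mu <- t(vapply(labs, function(l) colMeans(Xtr[gtr == l, , drop = FALSE]), numeric(p)))
    centered <- Xtr - mu[as.integer(gtr), , drop = FALSE]
    S <- crossprod(centered) / (nrow(Xtr) - k)
    Sinv <- tryCatch(chol2inv(chol(S)), error = function(e) {
      eps <- 1e-8 * sum(diag(S)) / p
      chol2inv(chol(S + diag(eps, p)))
    })
    # equal priors: the prior term is constant across classes
    disc <- X[i, , drop = FALSE] %*% Sinv %*% t(mu) - 0.5 * diag(mu %*% Sinv %*% t(mu))
    out[i, ] <- disc
  }
  out
}

#' Assign calls to individuals by leave-one-out linear discriminant analysis
#'
#' For each call, a linear discriminant model (equal prior probability
#' `1 / n_individuals` per individual, pooled within-individual covariance)
#' is fitted on all remaining calls and the held-out call is assigned to the
#' individual with the highest posterior probability. Posterior ties are
#' broken in favour of the lexicographically smallest individual label and
#' flagged in the `tie` column.
#'
#' The cross-validated fit is delegated to [MASS::lda()]; if the pooled
#' covariance is singular for `MASS::lda`, a ridge-regularized pooled
#' covariance (diagonal inflation `1e-8 * trace/dim`) is used instead and a
#' warning is raised. Constant feature columns are dropped with a warning.
#'
#' @param data A call dataset; every individual needs at least 2 calls.
#' @param features Feature selection: `NULL` (all features), a character
#'   vector, or a [feature_spec()].
#' @return An `assignment_result` tibble with columns `call`, `individual`
#'   (true), `predicted`, `correct`, `tie`.
#' @examples
#' calls <- generate_population(n_individuals = 4, calls_per_individual = 6, seed = 1)
#' res <- classify_loo_lda(calls)
#' mean(res$correct)
#' @export
classify_loo_lda <- function(data, features = NULL) {
  data <- call_dataset(data)
  check_discrimination_ready(data)
  feats <- resolve_features(data, features)
  X <- as.matrix(data[feats])
  keep <- apply(X, 2, sd) > 0
  if (!all(keep)) {
    warn(
      sprintf("dropping constant feature(s): %s", paste(feats[!keep], collapse = ", ")),
      class = "vocalid_feature_warning"
    )
    X <- X[, keep, drop = FALSE]
    feats <- feats[keep]
  }
  if (ncol(X) == 0L) {
    abort("no non-constant features left", class = "vocalid_validation_error")
  }
  g <- factor(data$individual)
  k <- nlevels(g)
  scores <- tryCatch(
    MASS::lda(x = X, grouping = g, prior = rep(1 / k, k), CV = TRUE)$posterior,
    error = function(e) NULL
  )
  # MASS::lda signals singular folds either by erroring or by NA posteriors
  if (is.null(scores) || anyNA(scores)) {
    warn(
      "singular pooled covariance; using ridge-regularized leave-one-out LDA",
      class = "vocalid_regularization_warning"
    )
    scores <- loo_lda_scores(X, g)
  }
  am <- argmax_lex(scores)
  new_assignment_result(
    call = data$call,
    individual = data$individual,
    predicted = am$predicted,
    tie = am$tie,
    classifier = "loo_lda",
    features = feats
  )
}

#' Assign calls to individuals by average similarity score
#'
#' For each query call, the similarity scores to every other call of each
#' individual are averaged and the call is assigned to the individual with
#' the highest average score — the standard decision rule for spectrogram
#' cross-correlation matrices. By default the query call's self-score is
#' excluded from its own individual's average (`exclude_self = TRUE`), the
#' analogue of leave-one-out cross-validation; including it would leak a
#' perfect self-match. Ties go to the lexicographically smallest label and
#' are flagged.
#'
#' @param similarity A [similarity_matrix()]. With `exclude_self = TRUE`
#'   every individual needs at least 2 calls, otherwise the self-excluded
#'   average over its own calls would be empty.
#' @param exclude_self Exclude the diagonal self-score from the query call's
#'   own individual average? Default `TRUE`.
#' @return An `assignment_result` tibble (see [classify_loo_lda()]).
#' @export
classify_similarity <- function(similarity, exclude_self = TRUE) {
  if (!inherits(similarity, "similarity_matrix")) {
    abort("`similarity` must be a similarity_matrix", class = "vocalid_parameter_error")
  }
  S <- similarity$scores
  ind <- similarity$individuals
  counts <- table(ind)
  if (length(counts) < 2L) {
    abort("discrimination needs at least 2 individuals", class = "vocalid_validation_error")
  }
  if (exclude_self && any(counts < 2L)) {
    abort(
      sprintf(
        "individual(s) with a single call cannot be scored with self-exclusion: %s",
        paste(names(counts[counts < 2L]), collapse = ", ")
      ),
      class = "vocalid_validation_error"
    )
  }
  labs <- sort(unique(ind))
  n <- nrow(S)
  M <- vapply(labs, function(l) as.numeric(ind == l), numeric(n))
  tot <- S %*% M
  cnt <- matrix(as.numeric(counts[labs]), n, length(labs), byrow = TRUE)
  if (exclude_self) {
    own <- cbind(seq_len(n), match(ind, labs))
    tot[own] <- tot[own] - diag(S)
    cnt[own] <- cnt[own] - 1
  }
  avg <- tot / cnt
  colnames(avg) <- labs
  am <- argmax_lex(avg)
  new_assignment_result(
    call = colnames(S),
    individual = unname(ind),
    predicted = am$predicted,
    tie = am$tie,
    classifier = "similarity",
    features = "similarity"
  )
}
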