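#' Confusion matrix of call assignments
#'
#' Rows are the individuals calls truly belong to, columns the individuals
#' calls were assigned to; entries count calls. Row sums therefore equal
#' each individual's call count.
#'
#' @param x An `assignment_result` (from [classify_loo_lda()] or
#'   [classify_similarity()]) or any data frame with `individual` and
#'   `predicted` columns.
#' @return A `confusion_matrix` (integer matrix with identical row and
#'   column labels).
#' @export
confusion_matrix <- function(x) {
  if (inherits(x, "confusion_matrix")) {
    return(x)
  }
  if (!is.data.frame(x) || !all(c("individual", "predicted") %in% names(x))) {
    abort(
      "`x` must be an assignment result with `individual` and `predicted` columns",
      class = "vocalid_parameter_error"
    )
  }
  labs <- sort(unique(c(x$individual, x$predicted)))
  cm <- table(
    factor(x$individual, levels = labs),
    factor(x$predicted, levels = labs)
  )
  cm <- unclass(cm)
  names(dimnames(cm)) <- c("true", "predicted")
  storage.mode(cm) <- "integer"
  structure(cm, class = c("confusion_matrix", class(cm)))
}

as_confusion <- function(x) {
  cm <- confusion_matrix(x)
  if (sum(cm) == 0L) {
    abort("empty confusion matrix", class = "vocalid_validation_error")
  }
  cm
}

#' Discrimination performance at the call level
#'
#' The proportion of single calls assigned to the correct individual: the
#' trace of the confusion matrix over the total call count.
#'
#' @param x An assignment result or a [confusion_matrix()].
#' @return A proportion in `[0, 1]`.
#' @export
call_accuracy <- function(x) {
  cm <- as_confusion(x)
  sum(diag(cm)) / sum(cm)
}

# Per-row plurality bookkeeping: is the row's unique modal column its own
# label, and is the mode tied?
row_plurality <- function(cm) {
  labs <- rownames(cm)
  present <- rowSums(cm) > 0L
  modal_own <- logical(length(labs))
  tied <- logical(length(labs))
  for (i in which(present)) {
    row <- cm[i, ]
    mx <- max(row)
    winners <- which(row == mx)
    tied[i] <- length(winners) > 1L
    modal_own[i] <- !tied[i] && colnames(cm)[winners] == labs[i]
  }
  list(correct = modal_own, tied = tied, present = present)
}

#' Discrimination performance at the individual level (plurality rule)
#'
#' An individual's whole call set is attributed to the individual that
#' received the most of its calls (the plurality, or "majority criterion":
#' a strict mode, not necessarily more than 50%). An individual is scored
#' correct when the unique modal column of its row is its own label; tied
#' modes are conservatively scored incorrect and counted (see
#' [discrimination_summary()]). This is how a 40% plurality of correctly
#' assigned calls can still identify every individual correctly, so
#' individual-level accuracy can far exceed call-level accuracy.
#'
#' @inheritParams call_accuracy
#' @return A proportion in `[0, 1]`: correctly attributed individuals over
#'   individuals with at least one call.
#' @export
individual_accuracy <- function(x) {
  cm <- as_confusion(x)
  pl <- row_plurality(cm)
  sum(pl$correct) / sum(pl$present)
}

#' Summarise discrimination at both levels
#'
#' @inheritParams call_accuracy
#' @return A one-row tibble: `call_accuracy`, `individual_accuracy`,
#'   `n_individuals`, `n_calls`, and `ties` (individuals whose plurality was
#'   tied and therefore scored incorrect).
#' @examples
#' cm <- matrix(c(15, 3, 2, 2, 15, 3, 7, 5, 8), 3, 3, byrow = TRUE,
#'              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' discrimination_summary(structure(cm, class = c("confusion_matrix", "matrix")))
#' @export
discrimination_summary <- function(x) {
  cm <- as_confusion(x)
  pl <- row_plurality(cm)
  tibble(
    call_accuracy = sum(diag(cm)) / sum(cm),
    individual_accuracy = sum(pl$correct) / sum(pl$present),
    n_individuals = sum(pl$present),
    n_calls = sum(cm),
    ties = sum(pl$tied)
  )
}

#' Chance level of call discrimination
#'
#' With equal prior probability per individual, assigning calls at random
#' succeeds with probability `1 / n`: 50% for 2 individuals down to 1.9%
#' for 54.
#'
#' @param n_individuals Number of individuals (>= 2).
#' @return `1 / n_individuals`.
#' @export
chance_level <- function(n_individuals) {
  if (!is.numeric(n_individuals) || length(n_individuals) != 1L ||
    n_individuals < 2 || n_individuals != round(n_individuals)) {
    abort("n_individuals must be a single integer >= 2", class = "vocalid_parameter_error")
  }
  1 / n_individuals
}
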