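#' Pairwise call-similarity (cross-correlation score) matrix
#'
#' Wraps a square matrix of pairwise call similarities — typically spectrogram
#' cross-correlation scores in `[0, 1]` — together with the mapping from call
#' labels to individuals. Asymmetric input (template-vs-target direction) is
#' symmetrized by element-wise averaging with its transpose; when that
#' happens the result carries `attr(, "symmetrized") = TRUE`.
#'
#' @param scores Square numeric matrix with call labels as dimnames (row
#'   names may be omitted and are then taken from the column names). Values
#'   must lie in `[0, 1]`.
#' @param individuals Mapping from call label to individual label: either a
#'   named character vector or a call dataset / data frame with `call` and
#'   `individual` columns.
#' @return A `similarity_matrix` object (list with `scores` and
#'   `individuals`).
#' @export
similarity_matrix <- function(scores, individuals) {
  scores <- as.matrix(scores)
  if (nrow(scores) != ncol(scores)) {
    abort(
      sprintf("similarity matrix must be square, got %d x %d", nrow(scores), ncol(scores)),
      class = "vocalid_format_error"
    )
  }
  if (!is.numeric(scores) || anyNA(scores) || any(!is.finite(scores))) {
    abort("similarity scores must be finite numbers", class = "vocalid_format_error")
  }
  if (is.null(colnames(scores)) && is.null(rownames(scores))) {
    abort("similarity matrix needs call labels as dimnames", class = "vocalid_format_error")
  }
  if (is.null(rownames(scores))) rownames(scores) <- colnames(scores)
  if (is.null(colnames(scores))) colnames(scores) <- rownames(scores)
  if (!identical(rownames(scores), colnames(scores))) {
    abort("row and column call labels differ", class = "vocalid_validation_error")
  }
  if (anyDuplicated(colnames(scores))) {
    abort("duplicated call labels in similarity matrix", class = "vocalid_validation_error")
  }
  if (any(scores < -1e-8) || any(scores > 1 + 1e-8)) {
    abort("similarity scores must lie in [0, 1]", class = "vocalid_validation_error")
  }

  if (is.data.frame(individuals)) {
    individuals <- setNames(as.character(individuals$individual), individuals$call)
  }
  individuals <- setNames(as.character(individuals), names(individuals))
  missing <- setdiff(colnames(scores), names(individuals))
  if (length(missing)) {
    abort(
      sprintf(
        "no individual label for call(s): %s",
        paste(utils::head(missing, 5), collapse = ", ")
      ),
      class = "vocalid_validation_error"
    )
  }
  individuals <- individuals[colnames(scores)]

  symmetrized <- FALSE
  if (max(abs(scores - t(scores))) > 1e-12) {
    scores <- (scores + t(scores)) / 2
    symmetrized <- TRUE
  }

  structure(
    list(scores = scores, individuals = individuals),
    symmetrized = symmetrized,
    class = "similarity_matrix"
  )
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf(
    "<similarity_matrix> %d calls, %d individuals%s\n",
    ncol(x$scores), length(unique(x$individuals)),
    if (isTRUE(attr(x, "symmetrized"))) " (symmetrized on ingestion)" else ""
  ))
  invisible(x)
}

#' @export
dim.similarity_matrix <- function(x) dim(x$scores)

# Subset a similarity matrix to given individuals and/or call labels.
sm_subset <- function(sm, individuals = NULL, calls = NULL) {
  keep <- colnames(sm$scores)
  if (!is.null(individuals)) keep <- keep[sm$individuals[keep] %in% individuals]
  if (!is.null(calls)) keep <- intersect(keep, calls)
  structure(
    list(scores = sm$scores[keep, keep, drop = FALSE], individuals = sm$individuals[keep]),
    symmetrized = attr(sm, "symmetrized"),
    class = "similarity_matrix"
  )
}

#' Read and write similarity matrices
#'
#' On disk a similarity matrix is delimited text whose first column and
#' header row hold the call labels. Non-square input is a format error;
#' asymmetric input is symmetrized by averaging (see [similarity_matrix()]).
#'
#' @param path Path to a delimited text file.
#' @param individuals Call-to-individual mapping, as in [similarity_matrix()].
#' @param delim Field delimiter; `NULL` auto-detects tab vs comma.
#' @return `read_similarity_matrix()` returns a [similarity_matrix()];
#'   `write_similarity_matrix()` returns `path` invisibly.
#' @export
read_similarity_matrix <- function(path, individuals, delim = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "vocalid_format_error")
  }
  delim <- delim %||% sniff_delim(path)
  raw <- readr::read_delim(
    path,
    delim = delim,
    col_types = readr::cols(
      readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  labels <- raw[[1]]
  mat <- as.matrix(raw[-1])
  if (nrow(mat) != ncol(mat)) {
    abort(
      sprintf("%s: similarity table is not square (%d rows x %d score columns)", path, nrow(mat), ncol(mat)),
      class = "vocalid_format_error"
    )
  }
  rownames(mat) <- labels
  if (!setequal(labels, colnames(mat))) {
    abort(sprintf("%s: row and column call labels disagree", path), class = "vocalid_validation_error")
  }
  mat <- mat[, labels, drop = FALSE] # enforce row order on columns
  similarity_matrix(mat, individuals)
}

#' @param sm A similarity matrix.
#' @rdname read_similarity_matrix
#' @export
write_similarity_matrix <- function(sm, path, delim = ",") {
  df <- as_tibble(sm$scores, rownames = "call")
  readr::write_delim(df, path, delim = delim, progress = FALSE)
  invisible(path)
}
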