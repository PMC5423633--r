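# Columns of a call table that are never treated as acoustic features.
RESERVED_COLUMNS <- c("individual", "call", "population")

#' Validate a table of calls and their acoustic features
#'
#' A call dataset is the universal input of the package: one row per call,
#' a categorical `individual` label, a unique `call` label, and one or more
#' numeric feature columns (e.g. fundamental-frequency measuring points
#' `F1`..`F20` in Hz, `duration` in s, or whole-call spectral features
#' `minF`, `q25`, `dF`, `q50`, `q75`, `maxF` in Hz). An optional `population`
#' column carries site/population metadata and is ignored by all analyses.
#'
#' Individuals with fewer than two calls are tolerated here (a warning is
#' recorded) but rejected by every discrimination operation, because
#' leave-one-out evaluation needs at least two calls per individual.
#'
#' @param data A data frame with columns `individual`, `call` (synthesized
#'   from `individual` plus a running index when absent) and numeric feature
#'   columns. Row order is preserved.
#' @return A `call_dataset` tibble with `individual` and `call` as character
#'   columns followed by the feature columns.
#' @examples
#' calls <- tibble::tibble(
#'   individual = c("a", "a", "b", "b"),
#'   F1 = c(800, 810, 900, 905),
#'   F2 = c(1200, 1190, 1100, 1110)
#' )
#' call_dataset(calls)
#' @export
call_dataset <- function(data) {
  data <- as_tibble(data)
  if (!"individual" %in% names(data)) {
    abort("a call table needs an `individual` column", class = "vocalid_format_error")
  }
  data$individual <- as.character(data$individual)
  if (anyNA(data$individual)) {
    abort("`individual` labels must not be missing", class = "vocalid_format_error")
  }
  if (!"call" %in% names(data)) {
    # deterministic synthesis: individual label + running index within individual
    idx <- stats::ave(seq_len(nrow(data)), data$individual, FUN = seq_along)
    data$call <- sprintf("%s_%03d", data$individual, idx)
  }
  data$call <- as.character(data$call)
  if (anyDuplicated(data$call)) {
    dup <- unique(data$call[duplicated(data$call)])
    abort(
      sprintf("call labels must be unique; duplicated: %s", paste(dup, collapse = ", ")),
      class = "vocalid_validation_error"
    )
  }

  feats <- setdiff(names(data), RESERVED_COLUMNS)
  if (length(feats) == 0L) {
    abort("a call table needs at least one feature column", class = "vocalid_format_error")
  }
  for (f in feats) {
    if (!is.numeric(data[[f]])) {
      abort(
        sprintf("feature column `%s` is not numeric", f),
        class = "vocalid_format_error"
      )
    }
    bad <- which(!is.finite(data[[f]]))
    if (length(bad)) {
      abort(
        sprintf("non-finite value in feature `%s`, row %d", f, bad[1]),
        class = "vocalid_validation_error"
      )
    }
  }

  small <- names(which(table(data$individual) < 2L))
  if (length(small)) {
    warn(
      sprintf(
        "individual(s) with fewer than 2 calls (unusable for discrimination): %s",
        paste(small, collapse = ", ")
      ),
      class = "vocalid_validation_warning"
    )
  }

  keep <- intersect(RESERVED_COLUMNS, names(data))
  data <- data[c(keep, feats)]
  class(data) <- unique(c("call_dataset", class(data)))
  data
}

#' Feature columns of a call dataset
#'
#' @param data A call dataset (or any data frame shaped like one).
#' @return Character vector of feature column names, in column order.
#' @export
call_features <- function(data) {
  setdiff(names(data), RESERVED_COLUMNS)
}

# Discrimination tasks need >= 2 individuals, each with >= 2 calls.
check_discrimination_ready <- function(data) {
  counts <- table(data$individual)
  if (length(counts) < 2L) {
    abort("discrimination needs at least 2 individuals", class = "vocalid_validation_error")
  }
  small <- names(counts[counts < 2L])
  if (length(small)) {
    abort(
      sprintf(
        "every individual needs >= 2 calls for leave-one-out evaluation; offending: %s",
        paste(small, collapse = ", ")
      ),
      class = "vocalid_validation_error"
    )
  }
  invisible(data)
}

sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read and write call tables
#'
#' The canonical on-disk format is UTF-8 delimited text (comma or tab,
#' auto-detected from the header row): columns `individual`, `call`
#' (optional), then numeric features. Non-numeric feature cells are rejected
#' with the offending row and column named.
#'
#' @param path Path to a delimited text file.
#' @param delim Field delimiter; `NULL` (default) auto-detects tab vs comma.
#' @return `read_call_table()` returns a [call_dataset()];
#'   `write_call_table()` returns `path` invisibly.
#' @export
read_call_table <- function(path, delim = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "vocalid_format_error")
  }
  delim <- delim %||% sniff_delim(path)
  raw <- readr::read_delim(
    path,
    delim = delim,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (!"individual" %in% names(raw)) {
    abort(
      sprintf("%s: missing `individual` column", path),
      class = "vocalid_format_error"
    )
  }
  feats <- setdiff(names(raw), RESERVED_COLUMNS)
  for (f in feats) {
    num <- suppressWarnings(as.numeric(raw[[f]]))
    bad <- which(is.na(num) & !is.na(raw[[f]]))
    if (length(bad)) {
      abort(
        sprintf(
          "%s: non-numeric value %s in column `%s`, row %d",
          path, dQuote(raw[[f]][bad[1]]), f, bad[1]
        ),
        class = "vocalid_format_error"
      )
    }
    raw[[f]] <- num
  }
  call_dataset(raw)
}

#' @param data A call dataset.
#' @rdname read_call_table
#' @export
write_call_table <- function(data, path, delim = ",") {
  data <- call_dataset(data)
  readr::write_delim(data, path, delim = delim, progress = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
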