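#' Name a set of features defining a discrimination model
#'
#' A feature spec is a named, ordered set of feature columns to feed into a
#' classifier or into the individuality statistic. Most functions also accept
#' a bare character vector, or `NULL` for "all feature columns present".
#'
#' @param features Character vector of feature column names; non-empty,
#'   no duplicates.
#' @param name Optional label for the model; defaults to a compact summary
#'   of the feature names.
#' @return A `feature_spec` object.
#' @examples
#' feature_spec(c("F1", "F3", "F5"), name = "odd points")
#' @export
feature_spec <- function(features, name = NULL) {
  features <- as.character(features)
  if (length(features) == 0L) {
    abort("a feature spec needs at least one feature", class = "vocalid_parameter_error")
  }
  if (anyDuplicated(features)) {
    abort("duplicated feature names in spec", class = "vocalid_parameter_error")
  }
  name <- name %||% paste(features, collapse = "+")
  structure(list(name = name, features = features), class = "feature_spec")
}

#' @export
print.feature_spec <- function(x, ...) {
  cat("<feature_spec> ", x$name, ": ", paste(x$features, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Resolve NULL / character / feature_spec against the columns of `data`.
resolve_features <- function(data, spec) {
  if (is.null(spec)) {
    feats <- call_features(data)
  } else if (inherits(spec, "feature_spec")) {
    feats <- spec$features
  } else {
    feats <- as.character(spec)
  }
  missing <- setdiff(feats, names(data))
  if (length(missing)) {
    abort(
      sprintf("feature(s) not present in dataset: %s", paste(missing, collapse = ", ")),
      class = "vocalid_parameter_error"
    )
  }
  feats
}

spec_name <- function(spec, data = NULL) {
  if (is.null(spec)) {
    return("all_features")
  }
  if (inherits(spec, "feature_spec")) {
    return(spec$name)
  }
  paste(as.character(spec), collapse = "+")
}

#' Families of measuring-point models for pre-screening
#'
#' Builds a family of candidate discrimination models over fundamental
#' frequency measuring points `F1..Fk`, for screening which (and how many)
#' points carry individual identity information: all prefix sets
#' `F1..Fk` for `k = 2..n_points`, plus alternating-point subsets (every
#' 2nd point starting at F1 and at F2, every 3rd, every 4th). With
#' `n_points = 20` this yields 23 models.
#'
#' @param n_points Number of measuring points available (columns `F1` ..
#'   `F<n_points>` must exist in the target dataset).
#' @param duration Add `duration` to every model? Default `FALSE`.
#' @return Named list of [feature_spec()] objects.
#' @export
measuring_point_specs <- function(n_points = 20, duration = FALSE) {
  if (n_points < 4) {
    abort("need at least 4 measuring points", class = "vocalid_parameter_error")
  }
  pts <- function(i) paste0("F", i)
  specs <- list()
  for (k in 2:n_points) {
    specs[[sprintf("prefix_%02d", k)]] <- feature_spec(pts(1:k), sprintf("F1-F%d", k))
  }
  specs[["every2_odd"]] <- feature_spec(pts(seq(1, n_points, by = 2)), "every 2nd from F1")
  specs[["every2_even"]] <- feature_spec(pts(seq(2, n_points, by = 2)), "every 2nd from F2")
  specs[["every3"]] <- feature_spec(pts(seq(1, n_points, by = 3)), "every 3rd from F1")
  specs[["every4"]] <- feature_spec(pts(seq(1, n_points, by = 4)), "every 4th from F1")
  if (duration) {
    specs <- map(specs, function(s) feature_spec(c(s$features, "duration"), paste0(s$name, "+dur")))
  }
  specs
}
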