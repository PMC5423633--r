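# Identity information (bits) of one component from its ANOVA F and the
# number of individuals n; F = 1 (no between-individual signal) maps to 0.
hi_from_f <- function(f_stat, n) {
  log2((f_stat + n - 1) / n)
}

#' Beecher's information statistic H_S
#'
#' Quantifies the individual-identity information carried by a set of call
#' features, in bits. The features are standardized to zero mean and unit
#' variance, rotated by principal component analysis, and each component
#' contributes
#' \deqn{H_i = \log_2\!\frac{F + n - 1}{n}}
#' where `F` is the one-way ANOVA F-statistic of the component scores with
#' individual as the factor and `n` is the number of individuals. The total
#' is \eqn{H_S = \sum_i H_i} over all retained components. All components
#' are kept (no variance cutoff) and both significant and non-significant
#' F-values enter the sum; components with `F < 1` contribute negative
#' information, as the statistic prescribes.
#'
#' Zero-variance features are dropped with a warning before PCA;
#' numerically zero-variance principal components (rank deficiency) are
#' dropped silently since they carry no information. Unbalanced designs use
#' the ordinary one-way ANOVA F.
#'
#' @param data A call dataset; at least 2 individuals with 2 calls each.
#' @param features Feature selection: `NULL`, character vector, or
#'   [feature_spec()].
#' @return An `hs_result`: list with `n` (individuals), `n_calls`,
#'   `components` (tibble of per-component `sdev`, `F`, `h`), `hs` (total
#'   bits) and `features`. Supports [tidy()], [glance()] and `print()`.
#' @examples
#' calls <- generate_population(n_individuals = 10, calls_per_individual = 8, seed = 2)
#' compute_hs(calls)
#' @export
compute_hs <- function(data, features = NULL) {
  data <- call_dataset(data)
  check_discrimination_ready(data)
  feats <- resolve_features(data, features)
  X <- as.matrix(data[feats])
  keep <- apply(X, 2, sd) > 0
  if (!all(keep)) {
    warn(
      sprintf("dropping zero-variance feature(s) before PCA: %s", paste(feats[!keep], collapse = ", ")),
      class = "vocalid_feature_warning"
    )
    X <- X[, keep, drop = FALSE]
    feats <- feats[keep]
  }
  if (ncol(X) == 0L) {
    abort("no non-constant features left", class = "vocalid_validation_error")
  }

  pca <- prcomp(X, center = TRUE, scale. = TRUE)
  full_rank <- pca$sdev > 1e-8 * pca$sdev[1]
  scores <- pca$x[, full_rank, drop = FALSE]

  g <- factor(data$individual)
  k <- nlevels(g)
  N <- nrow(scores)
  fit <- lm(scores ~ g)
  ssw <- colSums(as.matrix(residuals(fit))^2)
  grand <- colMeans(scores)
  ssb <- colSums((as.matrix(fitted(fit)) - rep(grand, each = N))^2)
  f_stat <- (ssb / (k - 1)) / (ssw / (N - k))
  h_i <- hi_from_f(f_stat, k)

  structure(
    list(
      n = k,
      n_calls = N,
      components = tibble(
        component = colnames(scores),
        sdev = pca$sdev[full_rank],
        F = unname(f_stat),
        h = unname(h_i)
      ),
      hs = sum(h_i),
      features = feats
    ),
    class = "hs_result"
  )
}

#' @export
print.hs_result <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Beecher's information statistic\n  H_S = %.*f bits over %d components (%d individuals, %d calls)\n",
    digits, x$hs, nrow(x$components), x$n, x$n_calls
  ))
  invisible(x)
}

#' Number of individuals discriminable from an identity signal
#'
#' Converts identity information to a population size via
#' \deqn{N = P \times 2^{H_S}}
#' where `P` is the probability that a target individual's signature is not
#' duplicated by another group member. `P = 1` would demand unambiguous
#' signatures; `P = 0.9` mirrors the reliability of colour-ring
#' identification and is the conventional choice for monitoring.
#'
#' @param hs Identity information in bits: a number or an `hs_result`.
#' @param P Signature-uniqueness probability in `(0, 1]`. Default 0.9.
#' @return A one-row tibble: `hs`, `P`, `n_raw` (`P * 2^hs`) and `n`
#'   (`n_raw` rounded to the nearest integer).
#' @examples
#' estimate_discriminable_n(6.94, P = 0.9) # 111 individuals
#' estimate_discriminable_n(2.18, P = 0.9) # 4 individuals
#' @export
estimate_discriminable_n <- function(hs, P = 0.9) {
  if (inherits(hs, "hs_result")) hs <- hs$hs
  if (!is.numeric(hs) || length(hs) != 1L || !is.finite(hs)) {
    abort("`hs` must be a single finite number of bits", class = "vocalid_parameter_error")
  }
  if (!is.numeric(P) || length(P) != 1L || P <= 0 || P > 1) {
    abort("`P` must lie in (0, 1]", class = "vocalid_parameter_error")
  }
  n_raw <- P * 2^hs
  tibble(hs = hs, P = P, n_raw = n_raw, n = as.integer(round(n_raw)))
}
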