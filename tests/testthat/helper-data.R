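# Strongly separated classes: individual means many within-SDs apart.
make_separated_calls <- function(n_individuals = 4, n_calls = 6, p = 3,
                                 gap = 50, within_sd = 1, seed = 42) {
  set.seed(seed)
  mu <- matrix(1000 + gap * seq_len(n_individuals), n_individuals, p) +
    matrix(stats::rnorm(n_individuals * p, sd = gap / 5), n_individuals, p)
  ind <- rep(sprintf("ind%02d", seq_len(n_individuals)), each = n_calls)
  X <- mu[rep(seq_len(n_individuals), each = n_calls), , drop = FALSE] +
    matrix(stats::rnorm(n_individuals * n_calls * p, sd = within_sd),
      n_individuals * n_calls, p
    )
  colnames(X) <- paste0("F", seq_len(p))
  call_dataset(dplyr::bind_cols(
    tibble::tibble(individual = ind),
    tibble::as_tibble(as.data.frame(X))
  ))
}

# The illustrative 3-individual confusion structure: 20 calls per row,
# diagonal (15, 15, 8); the third individual keeps only a 40% plurality.
fig2_assignments <- function() {
  cm <- matrix(
    c(
      15, 3, 2,
      2, 15, 3,
      7, 5, 8
    ),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("A", "B", "C"), c("A", "B", "C"))
  )
  rows <- which(cm > 0, arr.ind = TRUE)
  data.frame(
    individual = rep(rownames(cm)[rows[, 1]], cm[rows]),
    predicted = rep(colnames(cm)[rows[, 2]], cm[rows]),
    stringsAsFactors = FALSE
  )
}

# Small symmetric similarity matrix with block structure.
make_block_similarity <- function(within = 0.9, between = 0.1,
                                  n_individuals = 2, n_calls = 2) {
  ind <- rep(sprintf("ind%02d", seq_len(n_individuals)), each = n_calls)
  n <- length(ind)
  S <- matrix(between, n, n)
  S[outer(ind, ind, "==")] <- within
  diag(S) <- 1
  calls <- sprintf("%s_c%d", ind, rep(seq_len(n_calls), n_individuals))
  dimnames(S) <- list(calls, calls)
  similarity_matrix(S, stats::setNames(ind, calls))
}
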