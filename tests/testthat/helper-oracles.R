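# Independent reference implementations, deliberately written as plain
# loops / textbook formulas so they share no code with the package.

# Leave-one-out LDA: pooled covariance, equal priors, argmax of the linear
# discriminant score; ties go to the first (lexicographically smallest) label.
oracle_loo_lda <- function(X, g) {
  g <- factor(g)
  labs <- levels(g)
  k <- length(labs)
  p <- ncol(X)
  pred <- character(nrow(X))
  for (i in seq_len(nrow(X))) {
    Xtr <- X[-i, , drop = FALSE]
    gtr <- g[-i]
    mu <- matrix(0, k, p)
    S <- matrix(0, p, p)
    for (j in seq_len(k)) {
      xs <- Xtr[gtr == labs[j], , drop = FALSE]
      mu[j, ] <- colMeans(xs)
      d <- sweep(xs, 2, mu[j, ])
      S <- S + t(d) %*% d
    }
    S <- S / (nrow(Xtr) - k)
    Si <- solve(S)
    sc <- numeric(k)
    for (j in seq_len(k)) {
      sc[j] <- X[i, ] %*% Si %*% mu[j, ] - 0.5 * mu[j, , drop = FALSE] %*% Si %*% mu[j, ]
    }
    pred[i] <- labs[which.max(sc)]
  }
  pred
}

# Average-similarity assignment as an explicit triple loop with
# self-exclusion and smallest-label tie-breaking.
oracle_similarity <- function(S, ind) {
  calls <- colnames(S)
  labs <- sort(unique(ind))
  pred <- character(length(calls))
  for (q in seq_along(calls)) {
    best <- -Inf
    best_lab <- NA_character_
    for (l in labs) {
      tot <- 0
      cnt <- 0
      for (c2 in seq_along(calls)) {
        if (c2 != q && ind[c2] == l) {
          tot <- tot + S[q, c2]
          cnt <- cnt + 1
        }
      }
      avg <- tot / cnt
      if (avg > best) {
        best <- avg
        best_lab <- l
      }
    }
    pred[q] <- best_lab
  }
  pred
}

# One-way ANOVA F from between/within mean squares.
oracle_anova_f <- function(x, g) {
  g <- factor(g)
  k <- nlevels(g)
  n <- length(x)
  grand <- mean(x)
  ssb <- 0
  ssw <- 0
  for (l in levels(g)) {
    v <- x[g == l]
    ssb <- ssb + length(v) * (mean(v) - grand)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

# Spearman correlation by the classic rank-difference formula (tie-free
# vectors only).
oracle_spearman <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Straight-line H_S: standardize, rotate by the eigenvectors of the
# correlation matrix, per-component F, sum of log2((F + n - 1) / n).
oracle_hs <- function(data, feats) {
  X <- as.matrix(data[feats])
  Xs <- scale(X)
  rot <- eigen(cor(X), symmetric = TRUE)$vectors
  scores <- Xs %*% rot
  n <- length(unique(data$individual))
  total <- 0
  for (j in seq_len(ncol(scores))) {
    f <- oracle_anova_f(scores[, j], data$individual)
    total <- total + log2((f + n - 1) / n)
  }
  total
}
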