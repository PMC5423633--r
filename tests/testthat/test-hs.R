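test_that("a component with F = 1 carries zero identity information", {
  expect_equal(vocalid:::hi_from_f(1, 7), 0)
  expect_equal(vocalid:::hi_from_f(1, 54), 0)
  # F below 1 contributes negative information, which is retained
  expect_lt(vocalid:::hi_from_f(0.5, 10), 0)
})

test_that("per-component ANOVA F matches the hand-computed toy example", {
  # 2 individuals x 3 calls, single feature: F = (54/1)/(4/4) = 54
  x <- c(1, 2, 3, 7, 8, 9)
  g <- rep(c("a", "b"), each = 3)
  expect_equal(oracle_anova_f(x, g), 54)

  d <- call_dataset(data.frame(individual = g, F1 = x))
  hs <- compute_hs(d)
  # one feature: the single standardized component preserves F exactly
  expect_equal(hs$components$F, 54, tolerance = 1e-9)
  expect_equal(hs$hs, log2((54 + 2 - 1) / 2), tolerance = 1e-9)

  # cross-check against the stock ANOVA machinery
  f_ref <- anova(lm(x ~ factor(g)))$`F value`[1]
  expect_equal(hs$components$F, f_ref, tolerance = 1e-9)
})

test_that("H_S is the sum of per-component information and obeys the F identity", {
  d <- generate_population(n_individuals = 8, calls_per_individual = 6, seed = 21)
  hs <- compute_hs(d)
  expect_equal(hs$hs, sum(hs$components$h), tolerance = 1e-9)
  expect_equal(hs$components$h, log2((hs$components$F + hs$n - 1) / hs$n), tolerance = 1e-12)
  expect_equal(nrow(hs$components), length(call_features(d)))
})

test_that("principal component scores are uncorrelated on full-rank data", {
  d <- generate_population(n_individuals = 10, calls_per_individual = 5, n_features = 6, seed = 4)
  X <- scale(as.matrix(d[call_features(d)]))
  pr <- prcomp(X)
  cv <- cov(pr$x)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-9)
})

test_that("compute_hs agrees with the straight-line implementation on the same data", {
  for (seed in c(1, 2, 3)) {
    d <- generate_population(
      n_individuals = 10, calls_per_individual = 10,
      n_features = 5, between_sd = 40, within_sd = 70, seed = seed
    )
    expect_equal(compute_hs(d)$hs, oracle_hs(d, call_features(d)), tolerance = 1e-9)
  }
})

test_that("stereotyped calls yield a large positive H_S on one component", {
  set.seed(6)
  d <- call_dataset(data.frame(
    individual = rep(c("a", "b", "c"), each = 4),
    F1 = rep(c(700, 1000, 1300), each = 4) + rnorm(12, sd = 1e-4)
  ))
  hs <- compute_hs(d)
  expect_equal(nrow(hs$components), 1)
  expect_gt(hs$components$F, 1e6)
  expect_gt(hs$hs, 15)
  expect_equal(hs$hs, hs$components$h)
})

test_that("degenerate inputs are rejected or repaired with a warning", {
  d <- generate_population(n_individuals = 4, calls_per_individual = 3, seed = 2)
  d$flat <- 1
  expect_warning(hs <- compute_hs(d), "zero-variance", class = "vocalid_feature_warning")
  expect_false("flat" %in% hs$features)

  single <- data.frame(individual = c("a", "a", "b"), F1 = c(1, 2, 3))
  expect_error(
    suppressWarnings(compute_hs(call_dataset(single))),
    class = "vocalid_validation_error"
  )
})

test_that("the discriminable-population estimate follows N = P * 2^HS", {
  expect_equal(estimate_discriminable_n(6.94, P = 0.9)$n, 111L)
  expect_equal(estimate_discriminable_n(2.18, P = 0.9)$n, 4L)
  expect_equal(estimate_discriminable_n(0, P = 1)$n, 1L)

  est <- estimate_discriminable_n(3.3, P = 0.45)
  expect_equal(est$n_raw, 0.45 * 2^3.3, tolerance = 1e-9)
  expect_equal(est$n, round(est$n_raw))

  # linear in P, strictly increasing in hs
  expect_equal(
    estimate_discriminable_n(3.3, P = 0.9)$n_raw,
    2 * estimate_discriminable_n(3.3, P = 0.45)$n_raw,
    tolerance = 1e-12
  )
  hs_grid <- seq(0, 8, by = 0.5)
  n_raw <- vapply(hs_grid, function(h) estimate_discriminable_n(h)$n_raw, numeric(1))
  expect_true(all(diff(n_raw) > 0))

  expect_error(estimate_discriminable_n(2, P = 1.2), class = "vocalid_parameter_error")
  expect_error(estimate_discriminable_n(2, P = 0), class = "vocalid_parameter_error")
})

test_that("hs_result supports tidy and glance", {
  d <- generate_population(n_individuals = 5, calls_per_individual = 4, seed = 9)
  hs <- compute_hs(d)
  expect_named(tidy(hs), c("component", "sdev", "F", "h"))
  g <- glance(hs)
  expect_equal(g$hs, hs$hs)
  expect_equal(g$n_individuals, 5)
})
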