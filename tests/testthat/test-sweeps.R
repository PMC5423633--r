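test_that("sweeps are bit-identical under the same seed", {
  d <- generate_population(n_individuals = 8, calls_per_individual = 5, n_features = 4, seed = 1)
  a <- sweep_population_size(d, sizes = c(2, 4, 8), n_reps = 4, seed = 42)
  b <- sweep_population_size(d, sizes = c(2, 4, 8), n_reps = 4, seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- sweep_population_size(d, sizes = c(2, 4, 8), n_reps = 4, seed = 43)
  expect_false(identical(as.data.frame(a), as.data.frame(c)))

  k1 <- sweep_calls_per_individual(d, calls = c(2, 4), n_reps = 3, seed = 7)
  k2 <- sweep_calls_per_individual(d, calls = c(2, 4), n_reps = 3, seed = 7)
  expect_identical(as.data.frame(k1), as.data.frame(k2))
})

test_that("strongly separated data stays at perfect call accuracy at every population size", {
  d <- make_separated_calls(n_individuals = 6, n_calls = 5, gap = 50, within_sd = 1)
  sw <- sweep_population_size(d, sizes = c(2, 4, 6), n_reps = 3, seed = 1)
  expect_true(all(sw$call_accuracy == 1))
  expect_true(all(sw$individual_accuracy == 1))
  expect_equal(nrow(sw), 9)
  expect_true(all(table(sw$step) == 3))
})

test_that("subsampling all available calls reproduces the un-subsampled result", {
  d <- generate_population(n_individuals = 5, calls_per_individual = 6, n_features = 4, seed = 3)
  sw <- sweep_calls_per_individual(d, calls = c(3, 6), n_reps = 2, seed = 9)
  full <- discrimination_summary(classify_loo_lda(d))
  at6 <- dplyr::filter(sw, step == 6)
  expect_equal(at6$call_accuracy, rep(full$call_accuracy, 2))
  expect_equal(at6$individual_accuracy, rep(full$individual_accuracy, 2))
})

test_that("individuals without enough calls are excluded from the call sweep with a warning", {
  d <- generate_population(n_individuals = 5, calls_per_individual = 6, n_features = 3, seed = 3)
  d_short <- d[!(d$individual == "ind01" & !d$call %in% c("ind01_c01", "ind01_c02", "ind01_c03")), ]
  msgs <- capture_warnings(
    sw <- sweep_calls_per_individual(d_short, calls = c(2, 6), n_reps = 2, seed = 1)
  )
  expect_true(any(grepl("excluding individual", msgs)))
  expect_true(all(sw$n_individuals == 4))
  expect_error(
    sweep_calls_per_individual(d, calls = 1:6, n_reps = 2, seed = 1),
    ">= 2", class = "vocalid_parameter_error"
  )
})

test_that("the similarity classifier drives sweeps the same way as LDA", {
  d <- make_separated_calls(n_individuals = 4, n_calls = 4, gap = 40, within_sd = 1)
  sm <- derive_similarity_matrix(d)
  sw <- sweep_population_size(
    method = "similarity", similarity = sm,
    sizes = c(2, 4), n_reps = 2, seed = 5
  )
  expect_true(all(sw$call_accuracy == 1))
  swc <- sweep_calls_per_individual(
    method = "similarity", similarity = sm,
    calls = c(2, 3), n_reps = 2, seed = 5
  )
  expect_true(all(swc$call_accuracy == 1))
})

test_that("monitorable population is open-ended on separable data and zero on noise", {
  d <- make_separated_calls(n_individuals = 6, n_calls = 5, gap = 50, within_sd = 1)
  m <- monitorable_population(d, n_calls = 4, criterion = "individual", n_reps = 3, seed = 2)
  expect_equal(m$n_monitorable, 6)
  expect_true(m$open_ended)
  expect_equal(m$threshold, 0.90)

  noise <- generate_population(
    n_individuals = 8, calls_per_individual = 6,
    n_features = 4, between_sd = 0, seed = 13
  )
  m0 <- monitorable_population(noise,
    n_calls = 4, criterion = "call",
    threshold = 0.9, n_reps = 3, seed = 2
  )
  expect_equal(m0$n_monitorable, 0L)
  expect_false(m0$open_ended)
})

test_that("the identity-information curve matches direct computation on its subsets", {
  d <- generate_population(n_individuals = 8, calls_per_individual = 5, n_features = 4, seed = 17)
  hc <- hs_population_curve(d, sizes = c(2, 5, 8), n_reps = 3, seed = 31)
  expect_equal(nrow(hc), 9)
  # size = n uses every individual: must equal the direct full-set H_S
  full <- compute_hs(d)$hs
  expect_equal(dplyr::filter(hc, size == 8)$hs, rep(full, 3), tolerance = 1e-12)
  # reproducibility
  hc2 <- hs_population_curve(d, sizes = c(2, 5, 8), n_reps = 3, seed = 31)
  expect_identical(as.data.frame(hc), as.data.frame(hc2))
})

test_that("individual-level accuracy saturates at 1 for very distinct individuals", {
  d <- generate_population(
    n_individuals = 10, calls_per_individual = 10,
    between_sd = 8 * 70, within_sd = 70, seed = 19
  )
  s <- discrimination_summary(classify_loo_lda(d))
  expect_equal(s$individual_accuracy, 1)
})
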