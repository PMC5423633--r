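test_that("a minimal well-formed call table is ingested and call ids are synthesized", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "individual,F1,F2",
    "a,800,1200",
    "a,810,1190",
    "b,900,1100"
  ), path)
  d <- suppressWarnings(read_call_table(path))
  expect_s3_class(d, "call_dataset")
  expect_equal(nrow(d), 3)
  expect_equal(length(unique(d$individual)), 2)
  expect_equal(anyDuplicated(d$call), 0)
  expect_equal(call_features(d), c("F1", "F2"))
})

test_that("non-numeric feature cells are rejected naming row and column", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "individual,call,F1,F5",
    "a,c1,800,700",
    "a,c2,810,oops",
    "b,c3,900,720",
    "b,c4,905,725"
  ), path)
  expect_error(read_call_table(path), "F5.*row 2", class = "vocalid_format_error")
})

test_that("missing individual column and non-finite features are format errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,F1", "a,800"), path)
  expect_error(read_call_table(path), "individual", class = "vocalid_format_error")
  expect_error(
    call_dataset(data.frame(individual = c("a", "a", "b", "b"), F1 = c(1, Inf, 3, 4))),
    "non-finite", class = "vocalid_validation_error"
  )
  expect_error(
    call_dataset(data.frame(individual = "a", call = "c", F1 = "x")),
    "not numeric", class = "vocalid_format_error"
  )
})

test_that("individuals with fewer than 2 calls warn at ingestion and error at classification", {
  df <- data.frame(individual = c("a", "a", "b"), F1 = c(1, 2, 3), F2 = c(4, 5, 6))
  expect_warning(d <- call_dataset(df), "fewer than 2 calls", class = "vocalid_validation_warning")
  expect_error(
    suppressWarnings(classify_loo_lda(d)),
    ">= 2 calls", class = "vocalid_validation_error"
  )
})

test_that("call table write/read round trip preserves labels and features", {
  d <- generate_population(
    n_individuals = 54, calls_per_individual = 3,
    n_features = 5, seed = 11
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_call_table(d, path)
  d2 <- read_call_table(path)
  expect_identical(d2$individual, d$individual)
  expect_identical(d2$call, d$call)
  for (f in call_features(d)) {
    expect_equal(d2[[f]], d[[f]], tolerance = 1e-12)
  }
})

test_that("tab-delimited tables are auto-detected", {
  d <- generate_population(n_individuals = 3, calls_per_individual = 2, n_features = 2, seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_call_table(d, path, delim = "\t")
  expect_equal(read_call_table(path)$F1, d$F1)
})

test_that("similarity matrices validate shape, labels and range", {
  sm <- make_block_similarity()
  expect_equal(dim(sm), c(4, 4))
  expect_true(all(sm$scores == t(sm$scores)))
  expect_false(isTRUE(attr(sm, "symmetrized")))

  S <- sm$scores
  S[1, 2] <- 2 # out of range
  expect_error(similarity_matrix(S, sm$individuals), "\\[0, 1\\]", class = "vocalid_validation_error")

  expect_error(
    similarity_matrix(matrix(0.5, 3, 4, dimnames = list(letters[1:3], letters[1:4])), c(a = "x")),
    "square", class = "vocalid_format_error"
  )
  expect_error(
    similarity_matrix(sm$scores, sm$individuals[-1]),
    "no individual label", class = "vocalid_validation_error"
  )
})

test_that("asymmetric scores are symmetrized by averaging and the operation is idempotent", {
  S <- matrix(c(1, 0.6, 0.4, 1), 2, 2, dimnames = list(c("c1", "c2"), c("c1", "c2")))
  sm <- similarity_matrix(S, c(c1 = "a", c2 = "b"))
  expect_equal(sm$scores[1, 2], 0.5)
  expect_equal(sm$scores[2, 1], 0.5)
  expect_true(attr(sm, "symmetrized"))

  sm2 <- similarity_matrix(sm$scores, sm$individuals)
  expect_equal(sm2$scores, sm$scores)
  expect_false(isTRUE(attr(sm2, "symmetrized")))
})

test_that("similarity matrix read/write round trips and rejects non-square files", {
  sm <- make_block_similarity(n_individuals = 3, n_calls = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_similarity_matrix(sm, path)
  sm2 <- read_similarity_matrix(path, sm$individuals)
  expect_equal(sm2$scores, sm$scores, tolerance = 1e-12)
  expect_identical(sm2$individuals, sm$individuals)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("call,c1,c2,c3", "c1,1,0.2,0.3", "c2,0.2,1,0.4"), bad)
  expect_error(read_similarity_matrix(bad, sm$individuals), "square", class = "vocalid_format_error")
})
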