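test_that("srs_sample draws valid, reproducible index sets", {
  scores <- rep(0:10, each = 20)
  expect_setequal(srs_sample(scores, length(scores), seed = 1),
                  seq_along(scores))
  expect_identical(srs_sample(scores, 50, seed = 7),
                   srs_sample(scores, 50, seed = 7))
  idx <- srs_sample(scores, 50, seed = 3)
  expect_length(idx, 50)
  expect_false(anyDuplicated(idx) > 0)
  expect_error(srs_sample(scores, 1000), "exceeds")
})

test_that("srs reproduces the population zero-proportion", {
  withr::with_seed(11, {
    scores <- c(rep(0, 10000), sample(1:40, 21251, TRUE))
  })
  p0 <- mean(scores == 0)
  hits <- vapply(1:40, function(s) {
    abs(mean(scores[srs_sample(scores, 750, seed = s)] == 0) - p0) <= 0.05
  }, logical(1))
  expect_gte(sum(hits), 38)
})

test_that("score_strata merges sparse tails to the minimum occupancy", {
  withr::with_seed(4, scores <- rpois(2000, 3))
  breaks <- score_strata(scores, min_count = 10)
  expect_true(all(stratum_counts(scores, breaks) >= 10))
  expect_equal(min(breaks), min(scores))
  expect_gt(length(breaks), 3)
})

test_that("symmetric weights are uniform for a triangular population", {
  withr::with_seed(6, {
    mass <- pmax(0, 1 - abs(0:20 - 10) / 11)
    scores <- sample(0:20, 30000, TRUE, prob = mass)
  })
  w <- derive_symmetric_weights(scores, n = 750)
  pos <- w$weight[w$weight > 0]
  expect_lt(max(pos) / min(pos), 1.5)
})

test_that("symmetric weights zero out empty strata and respect feasibility", {
  scores <- c(rep(0, 50), rep(1, 60), rep(2, 80), rep(3, 60), rep(4, 50))
  # force a stratum grid that includes an empty bin
  breaks <- c(0, 1, 2, 3, 4, 5, 6)
  w <- derive_symmetric_weights(scores, strata_edges = breaks, n = 100)
  expect_identical(w$weight[w$count == 0], 0)
  expect_equal(sum(w$allocation), 100, tolerance = 1e-9)

  one_sided <- rep(c(0, 0, 0, 1), 100)
  expect_error(derive_symmetric_weights(one_sided, n = 50), "one-sided")
})

test_that("stratified sampling symmetrizes a heavily skewed population", {
  spec <- synthetic_spec(seed = 11)
  delta <- calibrate_floor(spec, 0.32, seed = 5)
  spec$severity_offset <- as.numeric(delta)
  pop <- generate_responses(spec, seed = 21)
  scores <- simple_score(pop$data)
  expect_gt(describe_scores(scores)$skewness, 1.5)

  edges <- score_strata(scores)
  w <- derive_symmetric_weights(scores, edges, n = 750)
  skews <- vapply(1:20, function(s) {
    idx <- stratified_sample(scores, 750, edges, w, seed = s)
    describe_scores(scores[idx])$skewness
  }, numeric(1))
  expect_gte(sum(abs(skews) <= 0.3), 18)
})

test_that("stratified draws are exact-size, duplicate-free and reproducible", {
  withr::with_seed(14, scores <- rpois(5000, 4))
  idx1 <- stratified_sample(scores, 400, seed = 5)
  idx2 <- stratified_sample(scores, 400, seed = 5)
  expect_identical(idx1, idx2)
  expect_length(idx1, 400)
  expect_false(anyDuplicated(idx1) > 0)
  expect_true(all(idx1 >= 1 & idx1 <= 5000))
})

test_that("largest-remainder allocation splits evenly in the balanced case", {
  alloc <- largest_remainder(c(5, 5), 10, c(100, 100))
  expect_identical(alloc, c(5L, 5L))
  alloc2 <- largest_remainder(c(3.4, 3.3, 3.3), 10, c(10, 10, 10))
  expect_identical(sum(alloc2), 10L)
})

test_that("symmetrized samples center mean on median better than srs", {
  spec <- synthetic_spec(seed = 11)
  spec$severity_offset <- 1.2
  pop <- generate_responses(spec, seed = 33)
  scores <- simple_score(pop$data)
  edges <- score_strata(scores)
  w <- derive_symmetric_weights(scores, edges, n = 750)
  wins <- vapply(1:20, function(s) {
    srs <- scores[srs_sample(scores, 750, seed = s)]
    sym <- scores[stratified_sample(scores, 750, edges, w, seed = s)]
    abs(median(sym) - mean(sym)) < abs(median(srs) - mean(srs))
  }, logical(1))
  expect_gt(sum(wins), 10)
})
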