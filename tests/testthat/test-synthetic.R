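test_that("synthetic_spec validates its inputs", {
  spec <- synthetic_spec()
  expect_identical(spec$k, 2)
  expect_identical(dim(spec$pattern), c(12L, 2L))
  expect_equal(spec$factor_corr[1, 2], 0.4)
  expect_true(all(spec$uniquenesses >= 0 & spec$uniquenesses <= 1))

  bad_phi <- matrix(c(1, 1.2, 1.2, 1), 2, 2)
  expect_error(synthetic_spec(factor_corr = bad_phi), "PSD")
  expect_error(synthetic_spec(pattern = matrix(1.2, 12, 1)), "communalities")
  expect_error(synthetic_spec(thresholds = c(0, -1, 1, 2)), "increasing")
})

test_that("generated codes respect the discretization contract", {
  pop <- generate_responses(synthetic_spec(n = 500), seed = 1)
  codes <- as.matrix(pop$data)
  expect_true(all(codes %in% 0:4))
  expect_identical(dim(codes), c(500L, 12L))
  expect_identical(dim(pop$latent), c(500L, 2L))
  expect_equal(pop$achieved_zero_rate, mean(rowSums(codes) == 0))

  pop2 <- generate_responses(synthetic_spec(n = 500), seed = 1)
  expect_identical(pop$data, pop2$data)
})

test_that("independent items yield a near-identity polychoric matrix", {
  spec <- synthetic_spec(n = 10000, pattern = matrix(0, 12, 2))
  pop <- generate_responses(spec, seed = 2)
  R <- polychoric(pop$data)$rho
  expect_lt(max(abs(R[upper.tri(R)])), 0.05)
})

test_that("one-factor loadings imply rho = lambda^2 between items", {
  spec <- synthetic_spec(n = 10000, k = 1, pattern = matrix(0.8, 12, 1),
                         factor_corr = matrix(1, 1, 1))
  pop <- generate_responses(spec, seed = 3)
  R <- polychoric(pop$data)$rho
  offdiag <- R[upper.tri(R)]
  expect_lt(max(abs(offdiag - 0.64)), 0.05)
})

test_that("marginal category proportions converge to the normal rectangles", {
  tau <- qnorm(c(0.2, 0.4, 0.6, 0.8))
  spec <- synthetic_spec(n = 50000, severity_offset = 0.5)
  pop <- generate_responses(spec, seed = 4)
  expected <- diff(c(0, pnorm(tau + 0.5), 1))
  observed <- tabulate(pop$data$item_01 + 1L, 5) / 50000
  expect_lt(max(abs(observed - expected)), 0.01)
})

test_that("floor calibration hits its target and is monotone in delta", {
  spec <- synthetic_spec(seed = 9)
  delta <- calibrate_floor(spec, 0.32, tolerance = 0.02, seed = 9)
  expect_gte(attr(delta, "achieved"), 0.30)
  expect_lte(attr(delta, "achieved"), 0.34)

  # larger offset (easier items) piles more respondents on the floor
  rates <- vapply(c(0, 1, 2), function(d) {
    s <- spec
    s$severity_offset <- d
    generate_responses(s, seed = 10)$achieved_zero_rate
  }, numeric(1))
  expect_true(all(diff(rates) > 0))

  # a deterministic function of spec and seed
  expect_identical(as.numeric(calibrate_floor(spec, 0.2, seed = 3)),
                   as.numeric(calibrate_floor(spec, 0.2, seed = 3)))

  expect_error(calibrate_floor(spec, 0), "in \\(0, 1\\)")
  expect_error(calibrate_floor(spec, 0.5, delta_range = c(-6, 0)),
               "unachievable")
})

test_that("uncensored pipeline recovers the latent truth end to end", {
  hits <- vapply(1:8, function(s) {
    spec <- synthetic_spec(n = 5000, k = 2)
    pop <- generate_responses(spec, seed = 1200 + s)
    if (pop$achieved_zero_rate > 0.05) return(NA)
    pa <- parallel_analysis(pop$data[seq_len(1500), ], n_replicates = 20,
                            seed = s)
    if (pa$n_factors != 2) return(FALSE)
    fit <- efa(pop$data, k = 2, seed = s)
    min(match_factors(spec$pattern, fit$pattern)$congruence) >= 0.95
  }, logical(1))
  expect_gte(sum(hits, na.rm = TRUE), 7)
})

test_that("floor_sweep emits one row per rate, reproducibly", {
  spec <- synthetic_spec(n = 3000)
  sw1 <- floor_sweep(spec, c(0.10, 0.30),
                     scheme = sampling_scheme("srs", n = 400),
                     n_samples = 4, pa_replicates = 10, seed = 5)
  expect_identical(nrow(sw1), 2L)
  expect_true(all(abs(sw1$achieved_zero_rate - sw1$target_zero_rate) < 0.05))
  sw2 <- floor_sweep(spec, c(0.10, 0.30),
                     scheme = sampling_scheme("srs", n = 400),
                     n_samples = 4, pa_replicates = 10, seed = 5)
  expect_identical(sw1$modal_factors, sw2$modal_factors)
  expect_identical(sw1$delta, sw2$delta)
})
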