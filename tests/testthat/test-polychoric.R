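test_that("bivariate normal CDF matches closed forms and numeric integration", {
  expect_equal(bvn_cdf(0, 0, 0), 0.25, tolerance = 1e-14)
  # Sheppard's formula at the origin
  for (r in c(-0.8, -0.3, 0.5, 0.9)) {
    expect_equal(bvn_cdf(0, 0, r), 0.25 + asin(r) / (2 * pi),
                 tolerance = 1e-12)
  }
  expect_equal(bvn_cdf(Inf, 1, 0.4), pnorm(1), tolerance = 1e-14)
  expect_equal(bvn_cdf(-Inf, 1, 0.4), 0, tolerance = 1e-14)

  skip_if_not_installed("pracma")
  dens <- function(x, y, r) {
    exp(-(x^2 - 2 * r * x * y + y^2) / (2 * (1 - r^2))) /
      (2 * pi * sqrt(1 - r^2))
  }
  for (case in list(c(0.5, -0.3, 0.6), c(-1, 1, -0.7), c(1.5, 0.5, 0.95),
                    c(0.2, 0.2, -0.97))) {
    num <- pracma::integral2(function(x, y) dens(x, y, case[3]),
                             -8, case[1], -8, case[2],
                             reltol = 1e-10)$Q
    expect_equal(bvn_cdf(case[1], case[2], case[3]), num, tolerance = 1e-4)
  }
})

test_that("estimate_thresholds inverts cumulative margins and collapses gaps", {
  expect_equal(estimate_thresholds(c(50, 50))$tau, 0, tolerance = 1e-12)
  th <- estimate_thresholds(c(8413, 1587))
  expect_equal(th$tau, qnorm(0.8413), tolerance = 1e-12)
  expect_equal(th$tau, 1.0, tolerance = 1e-3)

  gap <- estimate_thresholds(c(10, 0, 10))
  expect_identical(gap$collapsed, 1L)
  expect_length(gap$tau, 1)
  expect_false(gap$degenerate)

  one <- estimate_thresholds(c(0, 20, 0))
  expect_true(one$degenerate)
  expect_length(one$tau, 0)

  inc <- estimate_thresholds(c(5, 10, 30, 40, 15))
  expect_true(all(diff(inc$tau) > 0))
})

test_that("polychoric_pair handles independence and boundary tables", {
  ind <- polychoric_pair(matrix(25, 2, 2))
  expect_lt(abs(ind$rho), 1e-6)
  expect_true(ind$converged)

  conc <- polychoric_pair(matrix(c(50, 0, 0, 50), 2, 2))
  expect_equal(conc$rho, 0.9999)
  expect_true(conc$at_bound)
  disc <- polychoric_pair(matrix(c(0, 50, 50, 0), 2, 2))
  expect_equal(disc$rho, -0.9999)

  expect_error(polychoric_pair(matrix(c(10, 0, 20, 0), 2, 2)), "degenerate")
})

test_that("polychoric_pair agrees with a fine grid search of its likelihood", {
  for (seed in 1:12) {
    tab <- random_table(seed)
    fit <- polychoric_pair(tab)
    grid <- seq(-0.99, 0.99, by = 1e-4)
    rho_grid <- grid[which.max(polychoric_loglik(tab, grid))]
    expect_lt(abs(fit$rho - rho_grid), 1e-3)
    expect_lte(fit$loglik, 0)
  }
})

test_that("polychoric_pair has the transpose and reversal symmetries", {
  for (seed in c(3, 14)) {
    tab <- random_table(seed)
    r <- polychoric_pair(tab)$rho
    expect_equal(polychoric_pair(t(tab))$rho, r, tolerance = 1e-8)
    # reversing one item's category order negates the correlation;
    # reversing both preserves it
    expect_equal(polychoric_pair(tab[nrow(tab):1, ])$rho, -r,
                 tolerance = 1e-6)
    expect_equal(polychoric_pair(tab[nrow(tab):1, ncol(tab):1])$rho, r,
                 tolerance = 1e-6)
  }
})

test_that("polychoric estimates are consistent as n grows", {
  tau <- qnorm(c(0.3, 0.6, 0.85))
  errs <- vapply(c(1e3, 1e4, 1e5), function(n) {
    tab <- latent_normal_table(0.55, tau, tau, n, seed = 77)
    abs(polychoric_pair(tab)$rho - 0.55)
  }, numeric(1))
  expect_lt(errs[2], errs[1])
  expect_lt(errs[3], 0.01)
})

test_that("polychoric matrix recovers known structure and flags problems", {
  # two identical items are near-perfectly concordant
  withr::with_seed(2, x <- sample(0:4, 400, TRUE))
  dup <- tibble::tibble(a = x, b = x)
  expect_gt(polychoric(dup)$rho[1, 2], 0.999)

  # independent items: small off-diagonals
  withr::with_seed(3, {
    ind <- tibble::as_tibble(as.data.frame(matrix(sample(0:4, 5000 * 4, TRUE),
                                                  5000, 4)))
  })
  R <- polychoric(ind)$rho
  expect_lt(max(abs(R[upper.tri(R)])), 0.07)
  expect_equal(diag(R), rep(1, 4), ignore_attr = TRUE)
  expect_equal(R, t(R), tolerance = 1e-12)

  # known latent correlation 0.5
  spec <- synthetic_spec(n = 5000, k = 1, pattern = matrix(sqrt(0.5), 2, 1),
                         factor_corr = matrix(1, 1, 1))
  pop <- generate_responses(spec, seed = 4)
  expect_lt(abs(polychoric(pop$data)$rho[1, 2] - 0.5), 0.05)

  deg <- tibble::tibble(a = rep(0L, 30), b = rep(c(0L, 1L), 15))
  expect_error(polychoric(deg), "degenerate item")
  expect_error(polychoric(tibble::tibble(a = c(0L, NA), b = c(1L, 2L))),
               "complete")
})

test_that("smooth_psd clips eigenvalues and preserves PSD matrices", {
  I5 <- diag(5)
  out <- smooth_psd(I5)
  expect_false(out$smoothed)
  expect_identical(out$values, I5)

  # indefinite pseudo-correlation matrix
  R <- matrix(c(1, 0.9, -0.3, 0.9, 1, 0.9, -0.3, 0.9, 1), 3, 3)
  expect_lt(min(eigen(R)$values), -0.01)
  sm <- smooth_psd(R)
  expect_true(sm$smoothed)
  expect_gte(sm$min_eigenvalue_after, 0)
  expect_equal(diag(sm$values), rep(1, 3), ignore_attr = TRUE)
  expect_lt(min(eigen(sm$values)$values), 1e-6) # clipped, not inflated

  # equicorrelation at rho = -0.505 has min eigenvalue 1 + 2*rho = -0.01;
  # clipping such a mild violation barely moves the entries
  R2 <- equicorrelation(3, -0.505)
  expect_equal(min(eigen(R2)$values), -0.01, tolerance = 1e-12)
  sm2 <- smooth_psd(R2)
  expect_gte(sm2$min_eigenvalue_after, 0)
  expect_lt(max(abs(sm2$values - R2)), 0.02)
  expect_error(smooth_psd(matrix(c(1, 0.2, 0.3, 1), 2, 2)), "symmetric")
})
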