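# Shared fixtures, generated in code.

# Random contingency table with non-empty margins (categories 3..5).
random_table <- function(seed, n = 500) {
  withr::with_seed(seed, {
    repeat {
      C1 <- sample(3:5, 1)
      C2 <- sample(3:5, 1)
      probs <- matrix(rgamma(C1 * C2, 1), C1, C2)
      tab <- matrix(rmultinom(1, n, probs / sum(probs)), C1, C2)
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) return(tab)
    }
  })
}

# Discretize a bivariate normal draw into a contingency table with known
# latent correlation -- the ground-truth generator for consistency checks.
latent_normal_table <- function(rho, tau1, tau2, n, seed) {
  withr::with_seed(seed, {
    z1 <- rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    x <- findInterval(z1, tau1)
    y <- findInterval(z2, tau2)
    tab <- matrix(0, length(tau1) + 1, length(tau2) + 1)
    for (i in seq_len(n)) tab[x[i] + 1, y[i] + 1] <- tab[x[i] + 1, y[i] + 1] + 1
    tab
  })
}

# Small uncensored two-factor sample for pipeline tests.
two_factor_sample <- function(n = 750, seed = 101, severity_offset = 0) {
  spec <- synthetic_spec(n = n, k = 2, severity_offset = severity_offset)
  generate_responses(spec, seed = seed)$data
}

equicorrelation <- function(p, rho) {
  R <- matrix(rho, p, p)
  diag(R) <- 1
  R
}
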