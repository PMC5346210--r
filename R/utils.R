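# Internal helpers shared across modules.

# Evaluate `expr` under a fixed seed when one is supplied, otherwise use the
# ambient RNG stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

#' Derive a replicate seed from a master seed
#'
#' Counter-based seed derivation (two rounds of a Lehmer multiplicative
#' congruential step modulo the Mersenne prime 2^31 - 1), so that replicate
#' `i` of an experiment always sees the same stream regardless of execution
#' order or batching.
#'
#' @param master Integer master seed.
#' @param counter Non-negative integer replicate counter.
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, counter) {
  m <- 2147483647
  x <- (as.numeric(master) %% m + 1) %% m
  x <- (48271 * x) %% m
  x <- (x + as.numeric(counter) + 1) %% m
  x <- (48271 * x) %% m
  as.integer(x %% (m - 1) + 1)
}

#' Tucker congruence between loading matrices
#'
#' Column-by-column cosine similarity between two loading matrices, the
#' standard factor-matching index.
#'
#' @param a,b Numeric matrices with the same number of rows.
#' @return A `ncol(a)` by `ncol(b)` matrix of congruence coefficients.
#' @export
factor_congruence <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  stopifnot(nrow(a) == nrow(b))
  an <- sweep(a, 2, sqrt(colSums(a^2)), "/")
  bn <- sweep(b, 2, sqrt(colSums(b^2)), "/")
  crossprod(an, bn)
}

#' Match recovered factors to a reference pattern
#'
#' Finds the column permutation and signs of `b` maximizing the total
#' absolute Tucker congruence with `a` (exhaustive over permutations, so
#' intended for small numbers of factors).
#'
#' @param a Reference loading matrix (p x k).
#' @param b Recovered loading matrix (p x k).
#' @return A list with `matched` (reordered, sign-aligned `b`),
#'   `congruence` (per-column congruence with `a` after matching), and
#'   `mean_congruence`.
#' @export
match_factors <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  k <- ncol(a)
  stopifnot(ncol(b) == k, k <= 5)
  phi <- abs(factor_congruence(a, b))
  perms <- all_permutations(k)
  best <- NULL
  best_val <- -Inf
  for (i in seq_len(nrow(perms))) {
    val <- sum(phi[cbind(seq_len(k), perms[i, ])])
    if (val > best_val) {
      best_val <- val
      best <- perms[i, ]
    }
  }
  bm <- b[, best, drop = FALSE]
  signs <- sign(diag(factor_congruence(a, bm)))
  signs[signs == 0] <- 1
  bm <- sweep(bm, 2, signs, "*")
  cong <- diag(factor_congruence(a, bm))
  list(matched = bm, permutation = best, signs = signs,
       congruence = cong, mean_congruence = mean(cong))
}

all_permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1)
  out <- matrix(0L, 0, k)
  for (pos in seq_len(k)) {
    out <- rbind(out, cbind(sub[, seq_len(pos - 1), drop = FALSE], k,
                            sub[, seq(pos, k - 1)[seq_len(k - pos)],
                                drop = FALSE]))
  }
  storage.mode(out) <- "integer"
  dimnames(out) <- NULL
  out
}
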