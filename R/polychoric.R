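#' Item thresholds from category counts
#'
#' Step one of the two-step polychoric estimator: the threshold between
#' categories c and c+1 is the standard-normal quantile of the cumulative
#' proportion through c. Empty categories carry no threshold; they are
#' collapsed into the lower adjacent category (toward 0) and recorded.
#'
#' @param counts Non-negative integer vector of per-category counts
#'   (category 0 first).
#' @return A list with `tau` (strictly increasing finite thresholds),
#'   `collapsed` (0-based indices of empty categories merged away), and
#'   `degenerate` (`TRUE` when fewer than two categories are occupied, in
#'   which case no finite threshold exists).
#' @export
estimate_thresholds <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || anyNA(counts)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  n <- sum(counts)
  if (n < 1) stop("total count must be at least 1", call. = FALSE)
  empty <- which(counts == 0) - 1L
  occupied <- counts[counts > 0]
  if (length(occupied) < 2) {
    return(list(tau = numeric(0), collapsed = empty, degenerate = TRUE))
  }
  cum <- cumsum(occupied) / n
  tau <- qnorm(cum[-length(cum)])
  list(tau = tau, collapsed = empty, degenerate = FALSE)
}

#' Polychoric correlation of one item pair
#'
#' Two-step maximum likelihood on a contingency table of ordinal codes:
#' thresholds are fixed at the inverse-normal of the margin proportions,
#' then the latent bivariate-normal correlation maximizes the multinomial
#' log-likelihood of the table. Estimates are clamped to
#' \eqn{|\rho| \le 1 - 10^{-4}} so downstream eigendecompositions stay
#' finite; monotone likelihoods (e.g. perfectly concordant tables) converge
#' to the clamp.
#'
#' @param tab A contingency table (matrix of non-negative counts), rows for
#'   the first item's categories, columns for the second's. At least two
#'   non-empty rows and columns are required.
#' @param tol Convergence tolerance on rho.
#' @return A list with `rho`, `loglik`, `converged`, `at_bound`, `n`, and
#'   the two items' threshold vectors `tau_row`, `tau_col`.
#' @export
polychoric_pair <- function(tab, tol = 1e-7) {
  tab <- as.matrix(tab)
  .poly_pair_cpp(tab, tol)
}

#' Profile log-likelihood of a polychoric table
#'
#' Evaluates, for each value of `rho`, the multinomial log-likelihood of a
#' contingency table under the latent bivariate-normal model with
#' thresholds fixed from the margins — the function that
#' [polychoric_pair()] maximizes. Exposed so the maximizer can be audited
#' against direct search.
#'
#' @inheritParams polychoric_pair
#' @param rho Vector of correlations in (-1, 1).
#' @return Numeric vector of log-likelihood values.
#' @export
polychoric_loglik <- function(tab, rho) {
  .poly_loglik_cpp(as.matrix(tab), as.numeric(rho))
}

#' Eigenvalue-clipping PSD repair for a correlation matrix
#'
#' Pairwise polychoric matrices need not be positive semi-definite. This
#' clips eigenvalues at a small floor, reconstitutes the matrix, and
#' rescales to unit diagonal. Already-PSD input is returned unchanged.
#'
#' @param R Symmetric correlation matrix with unit diagonal.
#' @param floor Eigenvalue floor (default 1e-8).
#' @return A list with `values` (the repaired matrix), `smoothed` (logical),
#'   `min_eigenvalue_before`, `min_eigenvalue_after`.
#' @export
smooth_psd <- function(R, floor = 1e-8) {
  R <- as.matrix(R)
  if (max(abs(R - t(R))) > 1e-12) stop("R must be symmetric", call. = FALSE)
  e <- eigen(R, symmetric = TRUE)
  min_before <- min(e$values)
  if (min_before >= floor) {
    diag(R) <- 1
    return(list(values = R, smoothed = FALSE,
                min_eigenvalue_before = min_before,
                min_eigenvalue_after = min_before))
  }
  lam <- pmax(e$values, floor)
  V <- e$vectors
  Rs <- V %*% (lam * t(V))
  d <- sqrt(diag(Rs))
  Rs <- Rs / tcrossprod(d)
  Rs <- (Rs + t(Rs)) / 2
  diag(Rs) <- 1
  dimnames(Rs) <- dimnames(R)
  list(values = Rs, smoothed = TRUE,
       min_eigenvalue_before = min_before,
       min_eigenvalue_after = min(eigen(Rs, symmetric = TRUE)$values))
}

#' Polychoric correlation matrix of an ordinal dataset
#'
#' Assembles all pairwise two-step ML polychoric correlations of a
#' complete-case ordinal dataset into a symmetric unit-diagonal matrix,
#' PSD-smoothing it by eigenvalue clipping when required (always flagged).
#'
#' @inheritParams validate_likert
#' @param smooth Apply PSD repair when the pairwise matrix is indefinite.
#' @param tol Convergence tolerance passed to the pair estimator.
#' @return An object of class `"polychoric"`: a list with `rho` (the p x p
#'   matrix, item labels as dimnames), `thresholds` (per-item list from
#'   [estimate_thresholds()]), `n`, `n_categories`, `smoothed`,
#'   `min_eigenvalue_before`, `min_eigenvalue_after`, `converged` (logical
#'   pair matrix) and `n_at_bound` (pairs clamped at the boundary).
#' @export
polychoric <- function(data, n_categories = 5, smooth = TRUE, tol = 1e-7) {
  data <- validate_likert(data, n_categories = n_categories)
  if (anyNA(data)) {
    stop("missing data present: apply complete_cases() first", call. = FALSE)
  }
  labels <- names(data)
  thresholds <- lapply(data, function(col) {
    estimate_thresholds(tabulate(col + 1L, nbins = n_categories))
  })
  degenerate <- vapply(thresholds, `[[`, logical(1), "degenerate")
  if (any(degenerate)) {
    stop("degenerate item(s) with a single occupied category: ",
         paste(labels[degenerate], collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(data)
  storage.mode(X) <- "integer"
  fit <- .poly_matrix_cpp(X, n_categories, tol)
  R <- fit$rho
  dimnames(R) <- list(labels, labels)
  min_before <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  smoothed <- FALSE
  min_after <- min_before
  if (smooth && min_before < 0) {
    sm <- smooth_psd(R)
    R <- sm$values
    smoothed <- TRUE
    min_after <- sm$min_eigenvalue_after
  }
  structure(
    list(rho = R, thresholds = thresholds, n = nrow(data),
         n_categories = n_categories, smoothed = smoothed,
         min_eigenvalue_before = min_before,
         min_eigenvalue_after = min_after,
         converged = fit$converged, n_at_bound = fit$n_at_bound),
    class = "polychoric"
  )
}

#' @export
print.polychoric <- function(x, digits = 2, ...) {
  cat("Polychoric correlation matrix (", nrow(x$rho), " items, n = ", x$n,
      ")\n", sep = "")
  if (x$smoothed) {
    cat("PSD-smoothed: min eigenvalue ",
        format(x$min_eigenvalue_before, digits = 3), " -> ",
        format(x$min_eigenvalue_after, digits = 3), "\n", sep = "")
  }
  print(round(x$rho, digits))
  invisible(x)
}

#' Bivariate standard normal CDF
#'
#' \eqn{P(X \le x, Y \le y)} for a standard bivariate normal with
#' correlation `rho`, by high-accuracy Gauss-Legendre quadrature. Used for
#' the rectangle probabilities of the polychoric likelihood.
#'
#' @param x,y Numeric scalars (may be infinite).
#' @param rho Correlation in (-1, 1).
#' @return The joint lower-tail probability.
#' @export
bvn_cdf <- function(x, y, rho) {
  .bvn_cdf_cpp(x, y, rho)
}
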