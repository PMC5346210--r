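#' Minimum-residual factor extraction
#'
#' Extracts `k` factors from a correlation matrix by minimizing the sum of
#' squared off-diagonal residuals \eqn{\sum_{i<j} (r_{ij} - (\Lambda
#' \Lambda')_{ij})^2} over the uniquenesses, with loadings given by the
#' leading eigenstructure of the reduced matrix. Starting communalities are
#' the squared multiple correlations. Uniquenesses are clamped to `[0, 1]`
#' with Heywood cases flagged.
#'
#' @param R Correlation matrix (or `"polychoric"` object); must be PSD —
#'   smooth first if necessary (see [smooth_psd()]).
#' @param k Number of factors, `1 <= k < p`.
#' @return A list with `loadings` (p x k, columns ordered by decreasing sum
#'   of squares), `uniquenesses`, `communalities`, `heywood` (per-item
#'   logical), `converged`, `objective`, `objective_start`, and
#'   `residual_rms` (root-mean-square off-diagonal residual).
#' @export
fit_minres <- function(R, k) {
  if (inherits(R, "polychoric")) R <- R$rho
  R <- as.matrix(R)
  p <- ncol(R)
  if (k < 1 || k >= p) stop("need 1 <= k < p", call. = FALSE)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("R is not positive semi-definite; apply smooth_psd() first",
         call. = FALSE)
  }
  offdiag <- upper.tri(R)

  loadings_from_psi <- function(psi) {
    Rc <- R
    diag(Rc) <- 1 - psi
    e <- eigen(Rc, symmetric = TRUE)
    lam <- pmax(e$values[seq_len(k)], 0)
    e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(lam), k, k)
  }
  objective <- function(psi) {
    L <- loadings_from_psi(psi)
    sum((R - tcrossprod(L))[offdiag]^2)
  }

  smc <- tryCatch(1 - 1 / diag(solve(R)), error = function(e) rep(0.5, p))
  psi0 <- pmin(pmax(1 - smc, 1e-4), 1)
  f0 <- objective(psi0)
  opt <- optim(psi0, objective, method = "L-BFGS-B",
               lower = rep(1e-4, p), upper = rep(1, p),
               control = list(maxit = 500, factr = 1e4))
  L <- loadings_from_psi(opt$par)
  # order by explained variance, fix column signs
  ssq <- colSums(L^2)
  ord <- order(ssq, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  sgn <- apply(L, 2, function(col) if (sum(col) < 0) -1 else 1)
  L <- sweep(L, 2, sgn, "*")
  h2 <- rowSums(L^2)
  # Heywood: communality at/above 1, or a uniqueness pinned at the bound
  heywood <- h2 > 1 | opt$par <= 1e-4 + 1e-10
  psi <- pmin(pmax(1 - h2, 0), 1)
  res <- (R - tcrossprod(L))[offdiag]
  rownames(L) <- rownames(R)
  list(loadings = L, uniquenesses = psi, communalities = pmin(h2, 1),
       heywood = heywood, converged = opt$convergence == 0,
       objective = opt$value, objective_start = f0,
       residual_rms = sqrt(mean(res^2)))
}

# Geomin criterion value and gradient (k-th-root normalization).
geomin_vgq <- function(L, eps) {
  k <- ncol(L)
  L2 <- L^2 + eps
  pro <- exp(rowSums(log(L2)) / k)
  list(f = sum(pro), Gq = (2 / k) * (L / L2) * pro)
}

# Oblique gradient-projection rotation (Jennrich-style) for a given
# criterion; Tmat columns are kept at unit length.
gpa_oblique <- function(A, Tmat, eps, max_iter, tol) {
  Ti <- solve(Tmat)
  L <- A %*% t(Ti)
  vg <- geomin_vgq(L, eps)
  f <- vg$f
  G <- -t(t(L) %*% vg$Gq %*% Ti)
  al <- 1
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    Gp <- G - Tmat %*% diag(colSums(Tmat * G), ncol(Tmat), ncol(Tmat))
    s <- sqrt(sum(Gp^2))
    if (s < tol) {
      converged <- TRUE
      break
    }
    al <- 2 * al
    for (half in 0:20) {
      X <- Tmat - al * Gp
      Tt <- sweep(X, 2, sqrt(colSums(X^2)), "/")
      Ti <- solve(Tt)
      L <- A %*% t(Ti)
      vgt <- geomin_vgq(L, eps)
      if (vgt$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tmat <- Tt
    f <- vgt$f
    G <- -t(t(L) %*% vgt$Gq %*% Ti)
  }
  list(pattern = L, Phi = crossprod(Tmat), Tmat = Tmat, criterion = f,
       converged = converged)
}

#' Oblique Geomin rotation
#'
#' Rotates an unrotated loading matrix to minimize the Geomin criterion
#' \eqn{f(\Lambda) = \sum_i \big(\prod_j (\lambda_{ij}^2 +
#' \epsilon)\big)^{1/k}} over oblique rotations, by gradient projection
#' with multiple random starts (the identity start is always included and
#' the best criterion value is kept). Geomin is multimodal, hence the
#' restarts. The reproduced matrix \eqn{\Lambda \Phi \Lambda'} is invariant
#' under rotation.
#'
#' @param loadings Unrotated p x k loading matrix (from [fit_minres()]).
#' @param epsilon Geomin smoothing constant (default 0.01).
#' @param random_starts Number of random oblique starts in addition to the
#'   identity (default 10).
#' @param max_iter Maximum gradient-projection iterations per start.
#' @param tol Gradient-norm convergence tolerance.
#' @param seed Optional seed for the random starts.
#' @return A list with `pattern` (rotated loadings, columns ordered by
#'   explained variance with positive orientation), `Phi` (factor
#'   correlations), `criterion`, `converged`, and `Tmat`.
#' @export
rotate_geomin <- function(loadings, epsilon = 0.01, random_starts = 10,
                          max_iter = 1000, tol = 1e-6, seed = NULL) {
  A <- as.matrix(loadings)
  k <- ncol(A)
  if (epsilon <= 0) stop("epsilon must be positive", call. = FALSE)
  if (k == 1) {
    return(list(pattern = A, Phi = matrix(1, 1, 1), criterion = NA_real_,
                converged = TRUE, Tmat = matrix(1, 1, 1)))
  }
  starts <- with_seed_if(seed, {
    c(list(diag(k)), lapply(seq_len(random_starts), function(i) {
      M <- matrix(rnorm(k * k), k, k)
      sweep(M, 2, sqrt(colSums(M^2)), "/")
    }))
  })
  best <- NULL
  for (Tmat in starts) {
    fit <- tryCatch(gpa_oblique(A, Tmat, epsilon, max_iter, tol),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$criterion < best$criterion) best <- fit
  }
  if (is.null(best)) stop("Geomin rotation failed from every start", call. = FALSE)
  # order factors by explained pattern variance; orient positively
  ssq <- colSums(best$pattern^2)
  ord <- order(ssq, decreasing = TRUE)
  P <- best$pattern[, ord, drop = FALSE]
  Phi <- best$Phi[ord, ord, drop = FALSE]
  sgn <- apply(P, 2, function(col) if (sum(col) < 0) -1 else 1)
  P <- sweep(P, 2, sgn, "*")
  Phi <- diag(sgn, k, k) %*% Phi %*% diag(sgn, k, k)
  rownames(P) <- rownames(A)
  list(pattern = P, Phi = Phi, criterion = best$criterion,
       converged = best$converged, Tmat = best$Tmat)
}

#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' Overall and per-item KMO: the ratio of summed squared correlations to
#' summed squared correlations plus summed squared anti-image partial
#' correlations (computed from the inverse correlation matrix). Values
#' above 0.60 are conventionally required before factoring. A singular or
#' identity matrix yields an undefined-flag result rather than an error.
#'
#' @param R Correlation matrix (or `"polychoric"` object).
#' @return A list with `overall`, `per_item` (named), and `defined`
#'   (logical; `FALSE` when the measure is undefined).
#' @export
kmo <- function(R) {
  if (inherits(R, "polychoric")) R <- R$rho
  R <- as.matrix(R)
  p <- ncol(R)
  inv <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(inv) || !all(is.finite(inv))) {
    return(list(overall = NA_real_, per_item = rep(NA_real_, p),
                defined = FALSE))
  }
  d <- 1 / sqrt(diag(inv))
  Q <- -inv * tcrossprod(d)
  diag(Q) <- 0
  R0 <- R
  diag(R0) <- 0
  r2 <- R0^2
  q2 <- Q^2
  denom <- sum(r2) + sum(q2)
  if (denom < 1e-14) {
    return(list(overall = NA_real_, per_item = rep(NA_real_, p),
                defined = FALSE))
  }
  per_denom <- rowSums(r2) + rowSums(q2)
  per <- ifelse(per_denom < 1e-14, NA_real_, rowSums(r2) / per_denom)
  names(per) <- colnames(R)
  list(overall = sum(r2) / denom, per_item = per, defined = TRUE)
}

#' Salient-loading mask
#'
#' Marks loadings whose absolute value meets the salience threshold (0.40
#' by convention; negative loadings count by magnitude).
#'
#' @param pattern Loading matrix.
#' @param threshold Salience threshold (default 0.40).
#' @return Logical matrix of the same shape.
#' @export
salient_loadings <- function(pattern, threshold = 0.40) {
  abs(as.matrix(pattern)) >= threshold
}

#' Exploratory factor analysis: minres extraction, Geomin rotation
#'
#' The full EFA step for ordinal data: polychoric correlations (computed
#' here when `x` is raw item data), minimum-residual extraction of `k`
#' factors, and oblique Geomin rotation (skipped for `k = 1`, where the
#' unrotated solution is reported and \eqn{\Phi = [1]}).
#'
#' @param x Item data frame or a correlation matrix / `"polychoric"`
#'   object.
#' @param k Number of factors.
#' @inheritParams rotate_geomin
#' @inheritParams validate_likert
#' @return An object of class `"efa_fit"`: pattern matrix, factor
#'   correlations `Phi`, `uniquenesses`, `communalities`, `unrotated`
#'   loadings, `criterion_value`, `residual_rms`, `converged`, `heywood`,
#'   `k`, and the correlation matrix `R` used.
#' @export
efa <- function(x, k, n_categories = 5, epsilon = 0.01, random_starts = 10,
                max_iter = 1000, tol = 1e-6, seed = NULL) {
  R <- if (is.data.frame(x)) {
    polychoric(x, n_categories = n_categories)$rho
  } else if (inherits(x, "polychoric")) {
    x$rho
  } else {
    as.matrix(x)
  }
  ext <- fit_minres(R, k)
  rot <- rotate_geomin(ext$loadings, epsilon = epsilon,
                       random_starts = random_starts, max_iter = max_iter,
                       tol = tol, seed = seed)
  Lam <- rot$pattern
  Phi <- rot$Phi
  model <- Lam %*% Phi %*% t(Lam) + diag(ext$uniquenesses)
  res <- (R - model)[upper.tri(R)]
  structure(
    list(pattern = Lam, Phi = Phi,
         uniquenesses = ext$uniquenesses,
         communalities = ext$communalities,
         unrotated = ext$loadings,
         criterion_value = rot$criterion,
         residual_rms = sqrt(mean(res^2)),
         converged = ext$converged && rot$converged,
         heywood = ext$heywood,
         k = as.integer(k), epsilon = epsilon,
         item_labels = colnames(R), R = R),
    class = "efa_fit"
  )
}

#' @export
print.efa_fit <- function(x, digits = 2, salience = 0.40, ...) {
  cat("Exploratory factor analysis: minres extraction,",
      if (x$k > 1) "Geomin rotation" else "unrotated (k = 1)", "\n")
  cat("  k =", x$k, " residual rms =", format(x$residual_rms, digits = 3),
      if (any(x$heywood)) " [Heywood case(s) clamped]" else "", "\n")
  P <- round(x$pattern, digits)
  mark <- ifelse(salient_loadings(x$pattern, salience), "*", " ")
  out <- matrix(paste0(format(P), mark), nrow(P), ncol(P),
                dimnames = list(rownames(x$pattern),
                                paste0("F", seq_len(x$k))))
  print(out, quote = FALSE)
  if (x$k > 1) {
    cat("Factor correlations:\n")
    print(round(x$Phi, digits))
  }
  invisible(x)
}
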