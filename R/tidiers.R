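# Broom-style tidiers for the package's fitted objects.

#' Tidy a polychoric correlation matrix
#'
#' @param x A `"polychoric"` object.
#' @param ... Unused.
#' @return A tibble with one row per item pair: `item1`, `item2`, `rho`,
#'   `converged`.
#' @method tidy polychoric
#' @export
tidy.polychoric <- function(x, ...) {
  p <- ncol(x$rho)
  labels <- colnames(x$rho)
  idx <- which(upper.tri(x$rho), arr.ind = TRUE)
  tibble::tibble(
    item1 = labels[idx[, 1]],
    item2 = labels[idx[, 2]],
    rho = x$rho[idx],
    converged = x$converged[idx]
  )
}

#' @rdname tidy.polychoric
#' @method glance polychoric
#' @export
glance.polychoric <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_items = ncol(x$rho), smoothed = x$smoothed,
    min_eigenvalue_before = x$min_eigenvalue_before,
    min_eigenvalue_after = x$min_eigenvalue_after,
    n_at_bound = x$n_at_bound
  )
}

#' Tidy a parallel analysis
#'
#' @param x A `"parallel_analysis"` object.
#' @param ... Unused.
#' @return A tibble with `position`, `observed`, `reference_mean`,
#'   `retained`.
#' @method tidy parallel_analysis
#' @export
tidy.parallel_analysis <- function(x, ...) {
  tibble::tibble(
    position = seq_along(x$observed),
    observed = x$observed,
    reference_mean = x$reference_means,
    retained = seq_along(x$observed) <= x$n_factors
  )
}

#' @rdname tidy.parallel_analysis
#' @method glance parallel_analysis
#' @export
glance.parallel_analysis <- function(x, ...) {
  tibble::tibble(
    n_factors = x$n_factors, n = x$n, n_items = x$p,
    n_replicates = x$n_replicates, method = x$method
  )
}

#' Tidy an EFA fit
#'
#' @param x An `"efa_fit"` object.
#' @param salience Salience threshold used for the `salient` column.
#' @param ... Unused.
#' @return A tibble in long form: `item`, `factor`, `loading`, `salient`,
#'   plus per-item `uniqueness` and `communality`.
#' @method tidy efa_fit
#' @export
tidy.efa_fit <- function(x, salience = 0.40, ...) {
  P <- x$pattern
  tibble::tibble(
    item = rep(x$item_labels, times = x$k),
    factor = rep(paste0("F", seq_len(x$k)), each = nrow(P)),
    loading = as.vector(P),
    salient = as.vector(salient_loadings(P, salience)),
    uniqueness = rep(x$uniquenesses, times = x$k),
    communality = rep(x$communalities, times = x$k)
  )
}

#' @rdname tidy.efa_fit
#' @method glance efa_fit
#' @export
glance.efa_fit <- function(x, ...) {
  tibble::tibble(
    k = x$k, residual_rms = x$residual_rms,
    criterion_value = x$criterion_value,
    converged = x$converged, n_heywood = sum(x$heywood),
    min_factor_correlation = min(x$Phi),
    epsilon = x$epsilon
  )
}

#' Tidy a retention experiment
#'
#' @param x A `"retention_experiment"` object.
#' @param ... Unused.
#' @return The counts tibble: `n_factors`, `n_samples`, and the scheme
#'   label.
#' @method tidy retention_experiment
#' @export
tidy.retention_experiment <- function(x, ...) {
  dplyr::mutate(x$counts, scheme = x$scheme$kind)
}

#' @rdname tidy.retention_experiment
#' @method glance retention_experiment
#' @export
glance.retention_experiment <- function(x, ...) {
  tibble::tibble(
    scheme = x$scheme$kind, n_samples = x$n_samples, n = x$scheme$n,
    modal_factors = modal_factors(x),
    pa_replicates = x$pa_replicates, n_redraws = x$n_redraws,
    mean_skewness = mean(x$detail$skewness),
    mean_zero_proportion = mean(x$detail$zero_proportion)
  )
}
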