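#' Principal-component eigenvalues of a correlation matrix
#'
#' Full descending eigenvalue spectrum of a correlation matrix; for a unit
#' diagonal the spectrum sums to the number of items.
#'
#' @param R Symmetric correlation matrix (or a `"polychoric"` object).
#' @return Numeric vector of descending eigenvalues.
#' @export
pca_eigenvalues <- function(R) {
  if (inherits(R, "polychoric")) R <- R$rho
  R <- as.matrix(R)
  if (max(abs(R - t(R))) > 1e-8) stop("R must be symmetric", call. = FALSE)
  sort(eigen(R, symmetric = TRUE, only.values = TRUE)$values,
       decreasing = TRUE)
}

#' Reference eigenvalues by column permutation
#'
#' The comparison spectrum for parallel analysis on ordinal data: each
#' replicate independently permutes every item's column (preserving each
#' item's marginal category distribution while destroying inter-item
#' dependence), recomputes the polychoric matrix, and takes its
#' principal-component eigenvalues. Returns the per-position mean across
#' replicates.
#'
#' @inheritParams polychoric
#' @param n_replicates Number of permutation replicates (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of mean reference eigenvalues, with the full
#'   replicate-by-position spectrum matrix attached as attribute
#'   `"spectra"`.
#' @export
reference_eigenvalues <- function(data, n_replicates = 100, n_categories = 5,
                                  seed = NULL) {
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  data <- validate_likert(data, n_categories = n_categories)
  if (anyNA(data)) stop("missing data present", call. = FALSE)
  X <- as.matrix(data)
  storage.mode(X) <- "integer"
  n <- nrow(X)
  p <- ncol(X)
  spectra <- with_seed_if(seed, {
    t(vapply(seq_len(n_replicates), function(r) {
      Xp <- apply(X, 2, sample, size = n)
      storage.mode(Xp) <- "integer"
      fit <- .poly_matrix_cpp(Xp, n_categories, 1e-6)
      sort(eigen(fit$rho, symmetric = TRUE, only.values = TRUE)$values,
           decreasing = TRUE)
    }, numeric(p)))
  })
  means <- colMeans(spectra)
  attr(means, "spectra") <- spectra
  means
}

#' Mean-eigenvalue retention rule
#'
#' Retains the leading factors whose observed eigenvalue exceeds the mean
#' reference eigenvalue at the same position, stopping at the first
#' position that fails (contiguous rule).
#'
#' @param observed Descending observed eigenvalues.
#' @param reference_means Mean reference eigenvalues of equal length.
#' @return Integer number of factors to retain (possibly 0).
#' @export
retain_factors <- function(observed, reference_means) {
  if (length(observed) != length(reference_means)) {
    stop("observed and reference_means must have equal length", call. = FALSE)
  }
  above <- observed > reference_means
  if (!above[1]) return(0L)
  first_fail <- which(!above)
  if (length(first_fail) == 0) return(length(observed))
  as.integer(first_fail[1] - 1L)
}

#' Parallel analysis with polychoric correlations
#'
#' Decides the number of factors for an ordinal dataset: the observed
#' spectrum is the principal-component eigenvalues of the polychoric
#' matrix, the reference spectrum is the mean over column-permutation
#' replicates, and the mean-eigenvalue criterion retains the leading
#' positions where the observed eigenvalue exceeds the reference mean.
#'
#' @inheritParams reference_eigenvalues
#' @return An object of class `"parallel_analysis"`: a list with
#'   `observed`, `reference_means`, `reference_spectra`, `n_factors`,
#'   `n_replicates`, `method`, `seed`, `n`, `p`.
#' @export
parallel_analysis <- function(data, n_replicates = 100, n_categories = 5,
                              seed = NULL) {
  data <- validate_likert(data, n_categories = n_categories)
  pc <- polychoric(data, n_categories = n_categories)
  observed <- pca_eigenvalues(pc)
  ref <- reference_eigenvalues(data, n_replicates = n_replicates,
                               n_categories = n_categories, seed = seed)
  structure(
    list(observed = observed,
         reference_means = as.numeric(ref),
         reference_spectra = attr(ref, "spectra"),
         n_factors = retain_factors(observed, as.numeric(ref)),
         n_replicates = n_replicates,
         method = "column permutation",
         seed = seed, n = nrow(data), p = ncol(data)),
    class = "parallel_analysis"
  )
}

#' @export
print.parallel_analysis <- function(x, ...) {
  cat("Parallel analysis (polychoric, PCA extraction, mean-eigenvalue",
      "criterion)\n")
  cat("  n =", x$n, ", items =", x$p, ", replicates =", x$n_replicates,
      "(", x$method, ")\n")
  cat("  factors retained:", x$n_factors, "\n")
  k <- min(x$p, max(4, x$n_factors + 2))
  tab <- rbind(observed = round(x$observed[1:k], 3),
               reference = round(x$reference_means[1:k], 3))
  colnames(tab) <- paste0("ev", 1:k)
  print(tab)
  invisible(x)
}
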