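#' Repeated-sampling factor-retention experiment
#'
#' The core resampling experiment: repeatedly draw samples from a
#' population of complete ordinal responses under a sampling scheme, run
#' parallel analysis on each sample, and tabulate how many samples retain
#' one, two, three, ... factors. Per-replicate seeds are derived from the
#' master seed by counter-based hashing ([derive_seed()]), so results do
#' not depend on execution order. A replicate whose sample leaves some
#' item with a single occupied category cannot be factor-analysed; it is
#' flagged and re-drawn with a fresh derived seed (the redraw count is
#' recorded).
#'
#' @param data Population item data (complete cases; see
#'   [complete_cases()]).
#' @param scheme A [sampling_scheme()] (its `n` is the per-sample size).
#' @param n_samples Number of replicate samples (default 1000).
#' @param seed Master seed; drawn from the ambient RNG when `NULL`.
#' @param pa_replicates Parallel-analysis permutation replicates per sample
#'   (default 100).
#' @inheritParams validate_likert
#' @return An object of class `"retention_experiment"`: `counts` (tibble of
#'   `n_factors` vs `n_samples`), `detail` (per-replicate tibble with the
#'   derived seed, retained factor count, sample skewness and zero
#'   proportion), `scheme`, `n_samples`, `seed`, `pa_replicates`,
#'   `n_redraws`.
#' @export
run_retention_experiment <- function(data, scheme = sampling_scheme("srs"),
                                     n_samples = 1000, seed = NULL,
                                     pa_replicates = 100, n_categories = 5) {
  data <- validate_likert(data, n_categories = n_categories)
  if (anyNA(data)) stop("population must be complete-case filtered", call. = FALSE)
  if (nrow(data) < scheme$n) {
    stop("population smaller than the per-sample size", call. = FALSE)
  }
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  scores <- as.integer(rowSums(data))
  strata_edges <- NULL
  weights <- NULL
  if (scheme$kind == "stratified_symmetric") {
    strata_edges <- score_strata(scores, min_count = scheme$min_count)
    weights <- derive_symmetric_weights(scores, strata_edges, n = scheme$n)
  }
  one_replicate <- function(rep_seed) {
    idx <- draw_sample(scores, scheme, seed = rep_seed,
                       strata_edges = strata_edges, weights = weights)
    sample_data <- data[idx, , drop = FALSE]
    occupied <- vapply(sample_data, function(col) length(unique(col)),
                       integer(1))
    if (any(occupied < 2)) return(NULL)
    pa <- parallel_analysis(sample_data, n_replicates = pa_replicates,
                            n_categories = n_categories,
                            seed = derive_seed(rep_seed, 1))
    sc <- rowSums(sample_data)
    list(n_factors = pa$n_factors,
         skewness = describe_scores(sc)$skewness,
         zero_proportion = mean(sc == 0))
  }
  detail <- vector("list", n_samples)
  n_redraws <- 0L
  extra_counter <- n_samples
  for (r in seq_len(n_samples)) {
    rep_seed <- derive_seed(seed, r)
    res <- one_replicate(rep_seed)
    while (is.null(res)) {
      n_redraws <- n_redraws + 1L
      extra_counter <- extra_counter + 1L
      rep_seed <- derive_seed(seed, extra_counter)
      res <- one_replicate(rep_seed)
    }
    detail[[r]] <- tibble::tibble(
      replicate = r, seed = rep_seed, n_factors = res$n_factors,
      skewness = res$skewness, zero_proportion = res$zero_proportion
    )
  }
  detail <- dplyr::bind_rows(detail)
  counts <- detail |>
    dplyr::count(.data$n_factors, name = "n_samples") |>
    dplyr::arrange(.data$n_factors)
  structure(
    list(counts = counts, detail = detail, scheme = scheme,
         n_samples = n_samples, seed = seed,
         pa_replicates = pa_replicates, n_redraws = n_redraws),
    class = "retention_experiment"
  )
}

#' Modal retained factor count of an experiment
#'
#' The factor count retained by the largest number of replicate samples;
#' ties break toward the smaller count (parsimony).
#'
#' @param x A `"retention_experiment"`.
#' @return Integer modal factor count.
#' @export
modal_factors <- function(x) {
  stopifnot(inherits(x, "retention_experiment"))
  counts <- x$counts
  best <- counts$n_factors[counts$n_samples == max(counts$n_samples)]
  as.integer(min(best))
}

#' @export
print.retention_experiment <- function(x, ...) {
  cat("Retention experiment:", x$n_samples, "samples of n =", x$scheme$n,
      "under", x$scheme$kind, "\n")
  cat("  parallel-analysis replicates per sample:", x$pa_replicates, "\n")
  if (x$n_redraws > 0) cat("  degenerate replicates re-drawn:", x$n_redraws, "\n")
  print(as.data.frame(x$counts), row.names = FALSE)
  cat("  modal factor count:", modal_factors(x), "\n")
  invisible(x)
}

#' Representative sample of an experiment
#'
#' Re-draws the first replicate (in derived-seed order) whose retained
#' factor count equals the experiment's modal count — the sample used for
#' the detailed factor-structure report.
#'
#' @param data The population passed to [run_retention_experiment()].
#' @param experiment The corresponding `"retention_experiment"`.
#' @return The sample as a tibble with attributes `k` (its retained factor
#'   count) and `replicate`.
#' @export
select_representative_sample <- function(data, experiment) {
  stopifnot(inherits(experiment, "retention_experiment"))
  data <- tibble::as_tibble(data)
  mode_k <- modal_factors(experiment)
  row <- experiment$detail[experiment$detail$n_factors == mode_k, ][1, ]
  scores <- as.integer(rowSums(data))
  scheme <- experiment$scheme
  strata_edges <- NULL
  weights <- NULL
  if (scheme$kind == "stratified_symmetric") {
    strata_edges <- score_strata(scores, min_count = scheme$min_count)
    weights <- derive_symmetric_weights(scores, strata_edges, n = scheme$n)
  }
  idx <- draw_sample(scores, scheme, seed = row$seed,
                     strata_edges = strata_edges, weights = weights)
  out <- data[idx, , drop = FALSE]
  attr(out, "k") <- mode_k
  attr(out, "replicate") <- row$replicate
  out
}

#' Full factor-analysis report for one sample
#'
#' The complete per-sample analysis: KMO sampling adequacy (compared with
#' the conventional 0.60 bar), parallel analysis for the number of factors
#' (unless `k` is supplied), minres extraction with Geomin rotation, and
#' the salient-loading mask.
#'
#' @param sample_data Complete item data for one sample.
#' @param k Number of factors; decided by parallel analysis when `NULL`.
#' @param pa_replicates Parallel-analysis replicates.
#' @param salience Salience threshold for the loading mask.
#' @param seed Optional seed (parallel analysis and rotation starts).
#' @inheritParams validate_likert
#' @inheritParams rotate_geomin
#' @return An object of class `"efa_report"`: `kmo`, `suitable` (overall
#'   KMO above 0.60), `retention` (the `"parallel_analysis"`, or `NULL`
#'   when `k` was supplied), `k`, `efa` (the `"efa_fit"`, `NULL` when
#'   `k = 0`), and `salient` (logical mask).
#' @export
full_efa_report <- function(sample_data, k = NULL, pa_replicates = 100,
                            n_categories = 5, epsilon = 0.01,
                            random_starts = 10, salience = 0.40,
                            seed = NULL) {
  sample_data <- validate_likert(sample_data, n_categories = n_categories)
  if (anyNA(sample_data)) stop("sample must be complete", call. = FALSE)
  pc <- polychoric(sample_data, n_categories = n_categories)
  adequacy <- kmo(pc)
  retention <- NULL
  if (is.null(k)) {
    retention <- parallel_analysis(sample_data,
                                   n_replicates = pa_replicates,
                                   n_categories = n_categories, seed = seed)
    k <- retention$n_factors
  }
  fit <- NULL
  mask <- NULL
  if (k >= 1) {
    fit <- efa(pc, k = k, epsilon = epsilon, random_starts = random_starts,
               seed = if (is.null(seed)) NULL else derive_seed(seed, 2))
    mask <- salient_loadings(fit$pattern, threshold = salience)
  }
  structure(
    list(kmo = adequacy,
         suitable = isTRUE(adequacy$defined && adequacy$overall > 0.60),
         retention = retention, k = as.integer(k), efa = fit,
         salient = mask),
    class = "efa_report"
  )
}

#' @export
print.efa_report <- function(x, ...) {
  cat("Factor-analysis report\n")
  if (x$kmo$defined) {
    cat("  KMO overall:", round(x$kmo$overall, 3),
        if (x$suitable) "(adequate, > .60)" else "(below the .60 bar)", "\n")
  } else {
    cat("  KMO undefined: data unsuitable for factoring\n")
  }
  cat("  factors retained:", x$k, "\n")
  if (!is.null(x$efa)) print(x$efa)
  invisible(x)
}
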