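# ggplot2 displays for the package's result types.

#' Scree plot of a parallel analysis
#'
#' Observed polychoric-PCA eigenvalues against the mean reference
#' eigenvalues from column-permutation replicates; retained positions are
#' highlighted.
#'
#' @param object A `"parallel_analysis"` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot parallel_analysis
#' @export
autoplot.parallel_analysis <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("observed", "reference_mean"),
                        names_to = "series", values_to = "eigenvalue")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$eigenvalue,
                                   linetype = .data$series,
                                   shape = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$n_factors + 0.5,
                        linetype = "dotted") +
    ggplot2::labs(x = "Component", y = "Eigenvalue",
                  title = sprintf("Parallel analysis: %d factor(s) retained",
                                  object$n_factors)) +
    ggplot2::theme_minimal()
}

#' Loading heatmap of an EFA fit
#'
#' Tile display of the rotated pattern matrix with salient loadings
#' outlined.
#'
#' @param object An `"efa_fit"` object.
#' @param salience Salience threshold (default 0.40).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot efa_fit
#' @export
autoplot.efa_fit <- function(object, salience = 0.40, ...) {
  df <- tidy(object, salience = salience)
  df$item <- factor(df$item, levels = rev(object$item_labels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$factor, y = .data$item,
                                   fill = .data$loading)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::geom_tile(data = df[df$salient, , drop = FALSE],
                       fill = NA, color = "black", linewidth = 0.6) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$loading)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Geomin pattern matrix (k = %d)", object$k)) +
    ggplot2::theme_minimal()
}

#' Retention counts of an experiment
#'
#' Bar chart of how many replicate samples retained each factor count.
#'
#' @param object A `"retention_experiment"` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot retention_experiment
#' @export
autoplot.retention_experiment <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$n_factors),
                                   y = .data$n_samples)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Factors retained", y = "Samples",
                  title = sprintf("Retention over %d samples (%s)",
                                  object$n_samples, object$scheme$kind)) +
    ggplot2::theme_minimal()
}

#' Summary-score distribution plot
#'
#' Histogram of summary scores with the mean and median marked — the
#' at-a-glance check of skew and floor for a population or a drawn sample.
#'
#' @param scores Numeric vector of summary scores.
#' @return A ggplot.
#' @export
plot_score_distribution <- function(scores) {
  df <- tibble::tibble(score = as.numeric(scores))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(binwidth = 1, boundary = -0.5,
                            fill = "grey60", color = "white") +
    ggplot2::geom_vline(xintercept = mean(df$score), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = median(df$score), linetype = "solid") +
    ggplot2::labs(x = "Summary score", y = "Respondents") +
    ggplot2::theme_minimal()
}
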