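#' Simple random sample of respondents
#'
#' Draws `n` distinct row indices uniformly without replacement, so the
#' sample reproduces the population's (typically skewed) summary-score
#' distribution in expectation.
#'
#' @param scores Population summary scores (one per respondent).
#' @param n Sample size.
#' @param seed Optional integer seed.
#' @return Integer vector of `n` distinct row indices.
#' @export
srs_sample <- function(scores, n, seed = NULL) {
  N <- length(scores)
  if (n > N) stop("sample size exceeds population size", call. = FALSE)
  with_seed_if(seed, sample.int(N, n))
}

#' Summary-score strata
#'
#' Builds sampling strata over the integer summary-score range: each
#' observed integer score starts as its own stratum and sparse strata are
#' merged with their neighbor toward the median until every stratum holds
#' at least `min_count` respondents. Strata are returned as break points
#' `b`: stratum `s` contains scores in `[b[s], b[s+1])` (the last stratum
#' is closed on the right).
#'
#' @param scores Population summary scores.
#' @param min_count Minimum respondents per stratum (default 10).
#' @return Numeric vector of stratum break points.
#' @export
score_strata <- function(scores, min_count = 10) {
  lo <- min(scores)
  hi <- max(scores)
  breaks <- seq(lo, hi + 1)
  med <- median(scores)
  repeat {
    counts <- stratum_counts(scores, breaks)
    if (length(counts) <= 1 || all(counts >= min_count)) break
    s <- which(counts < min_count)[which.max(abs(stratum_mids(breaks)[counts < min_count] - med))]
    # merge toward the median
    mids <- stratum_mids(breaks)
    drop_idx <- if (mids[s] < med && s < length(counts)) s + 1
                else if (s > 1) s else s + 1
    breaks <- breaks[-drop_idx]
  }
  breaks
}

stratum_counts <- function(scores, breaks) {
  as.numeric(table(cut(scores, breaks = breaks, right = FALSE,
                       include.lowest = TRUE)))
}

stratum_mids <- function(breaks) {
  (head(breaks, -1) + breaks[-1]) / 2
}

stratum_index <- function(scores, breaks) {
  idx <- findInterval(scores, breaks, rightmost.closed = TRUE)
  idx[idx < 1] <- NA
  idx[idx > length(breaks) - 1] <- NA
  idx
}

#' Selection weights for an approximately symmetric sample
#'
#' Designs per-stratum selection weights so that a stratified sample has an
#' approximately symmetric summary-score distribution around the
#' population median. The target is a triangular mass over integer scores
#' centered at the median and truncated to the observed support; its
#' half-width is the widest one whose implied (truncated) skewness stays
#' within `symmetry_band`, so the sample covers as much of the score range
#' — as many degrees of severity — as approximate symmetry allows. For a
#' population whose median sits mid-support this reduces to an exactly
#' symmetric triangle. The weight of a stratum is its target mass divided
#' by its empirical mass; empty strata get weight zero. Expected draws
#' are capped at the available count, with the excess reallocated to the
#' nearest feasible strata toward the median.
#'
#' @param scores Population summary scores.
#' @param strata_edges Stratum break points (default from
#'   [score_strata()]).
#' @param n Intended sample size, used for the feasibility cap
#'   (default 750).
#' @param symmetry_band Maximum |skewness| of the target distribution
#'   (default 0.3, the conventional bound for "approximately symmetric").
#' @return A tibble with one row per stratum: `stratum`, `lower`, `upper`,
#'   `count`, `target_mass`, `allocation` (expected draws at size `n`),
#'   and `weight`.
#' @export
derive_symmetric_weights <- function(scores, strata_edges = NULL, n = 750,
                                     symmetry_band = 0.3) {
  med <- median(scores)
  lo <- min(scores)
  hi <- max(scores)
  if (min(med - lo, hi - med) < 1) {
    stop("symmetric target infeasible: support is one-sided around the ",
         "median (median ", med, ", range [", lo, ", ", hi, "])",
         call. = FALSE)
  }
  if (is.null(strata_edges)) strata_edges <- score_strata(scores)
  breaks <- strata_edges
  n_strata <- length(breaks) - 1
  if (n_strata < 3) stop("need at least 3 strata", call. = FALSE)
  counts <- stratum_counts(scores, breaks)
  s_vals <- seq(floor(lo), ceiling(hi))
  # only score values actually present can be drawn
  present <- s_vals %in% unique(scores)
  triangle <- function(h) {
    tv <- pmax(0, 1 - abs(s_vals - med) / (h + 1))
    tv[!present] <- 0
    tv
  }
  mass_skewness <- function(w) {
    w <- w / sum(w)
    mu <- sum(w * s_vals)
    m2 <- sum(w * (s_vals - mu)^2)
    m3 <- sum(w * (s_vals - mu)^3)
    if (m2 <= 0) 0 else m3 / m2^1.5
  }
  # widest half-width keeping the truncated triangle approximately
  # symmetric
  h_max <- max(med - lo, hi - med)
  feasible <- Filter(function(hh) abs(mass_skewness(triangle(hh))) <= symmetry_band,
                     seq_len(h_max))
  if (length(feasible) == 0) {
    stop("symmetric target infeasible: no triangular half-width keeps ",
         "|skewness| within ", symmetry_band, call. = FALSE)
  }
  h <- max(feasible)
  t_vals <- triangle(h)
  s_idx <- stratum_index(s_vals, breaks)
  target <- vapply(seq_len(n_strata),
                   function(s) sum(t_vals[which(s_idx == s)]), numeric(1))
  target[counts == 0] <- 0
  if (sum(target) <= 0) stop("symmetric target has no feasible mass", call. = FALSE)
  target <- target / sum(target)
  if (sum(counts[target > 0]) < n) {
    stop("symmetric target infeasible at n = ", n, ": only ",
         sum(counts[target > 0]), " respondents available in the ",
         "target-support strata", call. = FALSE)
  }
  alloc <- cap_allocation(n * target, counts,
                          order(abs(stratum_mids(breaks) - med)))
  weight <- ifelse(counts > 0, alloc / counts, 0)
  tibble::tibble(
    stratum = seq_len(n_strata),
    lower = head(breaks, -1), upper = breaks[-1],
    count = counts, target_mass = target,
    allocation = alloc, weight = weight
  )
}

# Cap expected allocations at stratum capacity, redistributing the excess
# to unfilled strata in `priority` order (nearest the median first),
# proportionally to their remaining target allocation.
cap_allocation <- function(alloc, counts, priority) {
  for (iter in seq_len(length(alloc) + 1)) {
    over <- alloc > counts
    if (!any(over)) break
    excess <- sum(alloc[over] - counts[over])
    alloc[over] <- counts[over]
    room <- counts - alloc
    open <- which(room > 1e-9 & alloc > 0)
    if (length(open) == 0) open <- which(room > 1e-9)
    if (length(open) == 0) break
    share <- alloc[open] + 1e-9
    alloc[open] <- alloc[open] + excess * share / sum(share)
  }
  alloc
}

#' Stratified sample with symmetrizing weights
#'
#' Draws a stratified random sample: per-stratum draw counts come from the
#' expected allocations by largest-remainder rounding (total exactly `n`),
#' and respondents are drawn uniformly without replacement within each
#' stratum.
#'
#' @param scores Population summary scores.
#' @param n Sample size (default 750).
#' @param strata_edges Optional stratum break points; derived from
#'   [score_strata()] when missing.
#' @param weights Optional weight table from [derive_symmetric_weights()];
#'   derived when missing.
#' @param seed Optional integer seed.
#' @return Integer vector of `n` distinct row indices.
#' @export
stratified_sample <- function(scores, n = 750, strata_edges = NULL,
                              weights = NULL, seed = NULL) {
  if (is.null(strata_edges)) strata_edges <- score_strata(scores)
  if (is.null(weights)) {
    weights <- derive_symmetric_weights(scores, strata_edges, n = n)
  }
  alloc <- weights$allocation
  counts <- weights$count
  draws <- largest_remainder(alloc, n, counts)
  idx_by_stratum <- stratum_index(scores, strata_edges)
  with_seed_if(seed, {
    out <- integer(0)
    for (s in seq_along(draws)) {
      if (draws[s] == 0) next
      pool <- which(idx_by_stratum == s)
      out <- c(out, pool[sample.int(length(pool), draws[s])])
    }
    out
  })
}

# Largest-remainder rounding of expected allocations to integers summing
# to n, respecting per-stratum capacity.
largest_remainder <- function(alloc, n, capacity) {
  base <- pmin(floor(alloc), capacity)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- alloc - floor(alloc)
    frac[base >= capacity] <- -Inf
    ord <- order(frac, decreasing = TRUE)
    for (s in ord) {
      if (rem == 0) break
      add <- min(1, capacity[s] - base[s], rem)
      if (add > 0) {
        base[s] <- base[s] + add
        rem <- rem - add
      }
    }
    # if fractional headroom ran out, fill wherever capacity remains
    if (rem > 0) {
      for (s in order(capacity - base, decreasing = TRUE)) {
        add <- min(capacity[s] - base[s], rem)
        base[s] <- base[s] + add
        rem <- rem - add
        if (rem == 0) break
      }
    }
  }
  if (rem != 0) stop("allocation infeasible: population too small", call. = FALSE)
  as.integer(base)
}

#' Sampling scheme descriptor
#'
#' A small descriptor for the two sample-selection strategies studied by
#' the package: `"srs"` (simple random sampling, preserving the skewed
#' population distribution) and `"stratified_symmetric"` (stratified
#' sampling with weights designed to symmetrize the summary-score
#' distribution around the population median).
#'
#' @param kind `"srs"` or `"stratified_symmetric"`.
#' @param n Sample size (default 750).
#' @param min_count Minimum stratum occupancy for stratified schemes.
#' @return An object of class `"sampling_scheme"`.
#' @export
sampling_scheme <- function(kind = c("srs", "stratified_symmetric"),
                            n = 750, min_count = 10) {
  kind <- match.arg(kind)
  structure(list(kind = kind, n = n, min_count = min_count),
            class = "sampling_scheme")
}

#' Draw one sample under a sampling scheme
#'
#' @param scores Population summary scores.
#' @param scheme A [sampling_scheme()].
#' @param seed Optional integer seed.
#' @param strata_edges,weights Optional precomputed stratification (for
#'   repeated draws from the same population).
#' @return Integer vector of selected row indices.
#' @export
draw_sample <- function(scores, scheme, seed = NULL, strata_edges = NULL,
                        weights = NULL) {
  stopifnot(inherits(scheme, "sampling_scheme"))
  if (scheme$kind == "srs") {
    srs_sample(scores, scheme$n, seed = seed)
  } else {
    if (is.null(strata_edges)) {
      strata_edges <- score_strata(scores, min_count = scheme$min_count)
    }
    stratified_sample(scores, n = scheme$n, strata_edges = strata_edges,
                      weights = weights, seed = seed)
  }
}
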