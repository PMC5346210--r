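#' Validate a respondent-by-item table of ordinal Likert codes
#'
#' Checks that `data` is a rectangular table of integer category codes in
#' `0 .. n_categories - 1` (or `NA` for missing), with at least two items and
#' unique item labels. Returns the data as a tibble of integer columns so
#' that downstream functions can assume a clean input.
#'
#' @param data A data frame, one respondent per row, one item per column.
#' @param n_categories Number of ordered categories per item; codes run from
#'   0 to `n_categories - 1`. Default 5 (the usual "none" to "extreme"
#'   difficulty scale of short disability screeners).
#' @return A tibble of integer columns.
#' @export
validate_likert <- function(data, n_categories = 5) {
  if (!is.data.frame(data)) {
    stop("`data` must be a data frame of item responses", call. = FALSE)
  }
  if (ncol(data) < 2) {
    stop("need at least two items (columns)", call. = FALSE)
  }
  labels <- names(data)
  if (anyDuplicated(labels)) {
    stop("item labels must be unique; duplicated: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(data)
  for (j in seq_along(out)) {
    col <- out[[j]]
    if (is.factor(col)) col <- as.character(col)
    if (is.character(col)) col <- suppressWarnings(as.numeric(col))
    if (!is.numeric(col)) {
      stop("column `", labels[j], "` is not numeric", call. = FALSE)
    }
    ok <- is.na(col) | (col == round(col))
    if (!all(ok)) {
      stop("column `", labels[j], "` row ", which(!ok)[1],
           ": non-integer code", call. = FALSE)
    }
    bad <- !is.na(col) & (col < 0 | col > n_categories - 1)
    if (any(bad)) {
      stop("column `", labels[j], "` row ", which(bad)[1], ": code ",
           col[which(bad)[1]], " outside 0..", n_categories - 1,
           call. = FALSE)
    }
    out[[j]] <- as.integer(col)
  }
  out
}

#' Read ordinal questionnaire responses from a CSV file
#'
#' Reads a CSV with a header row of item labels and one respondent per row.
#' Cells matching one of the `missing` tokens (by default the empty cell and
#' "NA") become missing values; any other non-integer or out-of-range cell
#' is an error, never silently coerced.
#'
#' @param path Path to the CSV file.
#' @inheritParams validate_likert
#' @param missing Character vector of tokens to treat as missing.
#' @return A validated tibble of integer item codes (with `NA` for missing).
#' @export
read_likert_csv <- function(path, n_categories = 5, missing = c("", "NA")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- suppressWarnings(
    readr::read_csv(path, na = missing, show_col_types = FALSE,
                    col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  )
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    stop("parse error: file is not rectangular (first problem at row ",
         probs$row[1], ")", call. = FALSE)
  }
  validate_likert(raw, n_categories = n_categories)
}

#' Keep only respondents with complete item data
#'
#' Complete-case filtering: drops every row with at least one missing item
#' response, preserving row order.
#'
#' @param data A data frame of item codes (see [validate_likert()]).
#' @return A tibble containing only the complete rows.
#' @export
complete_cases <- function(data) {
  data <- tibble::as_tibble(data)
  keep <- stats::complete.cases(data)
  if (!any(keep)) {
    stop("no complete rows: every respondent has missing item data",
         call. = FALSE)
  }
  data[keep, , drop = FALSE]
}

#' Simple-sum summary scores
#'
#' The simple scoring rule for short Likert questionnaires: each
#' respondent's score is the sum of their item codes, ranging from 0 to
#' `(n_categories - 1) * n_items` (0 to 48 for 12 five-category items).
#'
#' @inheritParams validate_likert
#' @return An integer vector of summary scores, one per row.
#' @export
simple_score <- function(data, n_categories = 5) {
  data <- validate_likert(data, n_categories = n_categories)
  if (anyNA(data)) {
    stop("missing data present: apply complete_cases() before scoring",
         call. = FALSE)
  }
  as.integer(rowSums(data))
}

#' Distributional summary of summary scores
#'
#' Computes the descriptive statistics conventionally reported for skewed
#' questionnaire score distributions: mean, SD, adjusted Fisher-Pearson
#' skewness with its classical standard error, quartiles (linear
#' interpolation), and the proportion of zero scores (the floor).
#'
#' The skewness estimator is
#' \eqn{g_1 = \frac{m_3}{m_2^{3/2}} \sqrt{n(n-1)}/(n-2)} with
#' \eqn{SE(g_1) = \sqrt{6n(n-1)/((n-2)(n+1)(n+3))}}.
#'
#' @param scores Integer or numeric vector of summary scores (n >= 4).
#' @return A one-row tibble with columns `n`, `mean`, `sd`, `skewness`,
#'   `skewness_se`, `skewness_defined`, `p25`, `p50`, `p75`,
#'   `zero_proportion`. When the scores are constant the skewness is
#'   undefined: `skewness` is `NA` and `skewness_defined` is `FALSE`.
#' @export
describe_scores <- function(scores) {
  scores <- as.numeric(scores)
  n <- length(scores)
  if (n < 4) stop("need at least 4 scores", call. = FALSE)
  if (anyNA(scores)) stop("scores must not contain missing values", call. = FALSE)
  m <- mean(scores)
  s <- stats::sd(scores)
  m2 <- mean((scores - m)^2)
  m3 <- mean((scores - m)^3)
  defined <- m2 > 0
  g1 <- if (defined) (m3 / m2^1.5) * sqrt(n * (n - 1)) / (n - 2) else NA_real_
  se <- sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
  q <- stats::quantile(scores, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(
    n = n, mean = m, sd = s,
    skewness = g1, skewness_se = se, skewness_defined = defined,
    p25 = q[1], p50 = q[2], p75 = q[3],
    zero_proportion = mean(scores == 0)
  )
}
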