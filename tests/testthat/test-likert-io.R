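test_that("read_likert_csv parses codes, missing cells and rejects bad input", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b,c", "0,0,0", "0,0,0", "0,0,0"), path)
  ds <- read_likert_csv(path)
  expect_s3_class(ds, "tbl_df")
  expect_identical(dim(ds), c(3L, 3L))
  expect_true(all(as.matrix(ds) == 0L))
  expect_false(anyNA(ds))

  writeLines(c("a,b", "1,5", "0,0"), path)
  expect_error(read_likert_csv(path, n_categories = 5), "code 5")

  writeLines(c("a,b", "1,", "0,0"), path)
  ds2 <- read_likert_csv(path)
  expect_true(is.na(ds2$b[1]))
  expect_false(is.na(ds2$a[1]))

  writeLines(c("a,b", "1,2,3", "0,0"), path)
  expect_error(read_likert_csv(path), "rectangular")
})

test_that("validate_likert enforces range, integrality and unique labels", {
  expect_error(validate_likert(data.frame(a = 0:4)), "two items")
  df <- data.frame(a = c(0L, 2L), b = c(4L, -1L))
  expect_error(validate_likert(df), "`b` row 2")
  df2 <- data.frame(a = c(0, 1.5), b = c(1, 2))
  expect_error(validate_likert(df2), "non-integer")
  df3 <- data.frame(a = 0:1, b = 1:2)
  names(df3) <- c("x", "x")
  expect_error(validate_likert(df3), "unique")
})

test_that("complete_cases drops exactly the rows with missing entries", {
  df <- tibble::tibble(a = c(0L, NA, 2L, 3L, 1L), b = c(1L, 0L, NA, 2L, 0L))
  out <- complete_cases(df)
  expect_identical(nrow(out), 3L)
  expect_identical(out$a, c(0L, 3L, 1L))

  expect_identical(complete_cases(df[4:5, ]), tibble::as_tibble(df[4:5, ]))
  all_na <- tibble::tibble(a = c(NA, 1L), b = c(0L, NA))
  expect_error(complete_cases(all_na), "no complete rows")
})

test_that("simple_score sums item codes and respects bounds", {
  twelve <- function(x) tibble::as_tibble(as.data.frame(matrix(x, 1, 12)))
  expect_identical(simple_score(twelve(0L)), 0L)
  expect_identical(simple_score(twelve(4L)), 48L)
  row <- twelve(0L)
  row[1, 1] <- 1L; row[1, 3] <- 2L
  expect_identical(simple_score(row), 3L)
  expect_error(simple_score(tibble::tibble(a = NA_integer_, b = 1L)),
               "complete_cases")
})

test_that("simple_score is permutation-equivariant over items and rows", {
  withr::with_seed(5, {
    df <- tibble::as_tibble(as.data.frame(matrix(sample(0:4, 120, TRUE), 10, 12)))
    s <- simple_score(df)
    perm_items <- df[, sample(12)]
    expect_identical(simple_score(perm_items), s)
    rp <- sample(10)
    expect_identical(simple_score(df[rp, ]), s[rp])
  })
})

test_that("describe_scores matches the adjusted Fisher-Pearson conventions", {
  d <- describe_scores(rep(0:4, each = 10))
  expect_equal(d$skewness, 0, tolerance = 1e-12)
  expect_true(d$p25 <= d$p50 && d$p50 <= d$p75)

  # SE(g1) closed form at the study sizes
  se_of <- function(n) describe_scores(seq_len(n) %% 7)$skewness_se
  expect_lt(abs(se_of(12226) - 0.02), 0.005)
  expect_equal(se_of(750), 0.0893, tolerance = 5e-4)

  const <- describe_scores(rep(3, 10))
  expect_false(const$skewness_defined)
  expect_true(is.na(const$skewness))
  expect_false(is.nan(const$skewness_se))

  # zero_proportion counts all-zero rows exactly
  withr::with_seed(8, {
    df <- tibble::as_tibble(as.data.frame(matrix(rbinom(240, 4, 0.1), 20, 12)))
    s <- simple_score(df)
    expect_equal(describe_scores(s)$zero_proportion,
                 mean(rowSums(df == 0) == 12))
  })
})

test_that("describe_scores reproduces a manual skewness computation", {
  x <- c(0, 0, 1, 2, 5, 9, 14)
  n <- length(x)
  m2 <- mean((x - mean(x))^2)
  m3 <- mean((x - mean(x))^3)
  g1 <- m3 / m2^1.5 * sqrt(n * (n - 1)) / (n - 2)
  expect_equal(describe_scores(x)$skewness, g1, tolerance = 1e-12)
  expect_equal(describe_scores(x)$p50, median(x))
})
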