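test_that("Fisher index matches hand arithmetic and handles degenerate separation", {
  x <- c(0, 1, 2, 3); y <- c(0, 0, 1, 1)
  expect_equal(fisher_index(x, y), 4)          # (2.5-0.5)^2 / (0.5+0.5)
  expect_equal(fisher_index(y, y), 1e6)        # zero variances, distinct means
  expect_equal(fisher_index(rep(2, 4), y), 0)  # zero variances, equal means
  expect_error(fisher_index(x, rep(0, 4)), "both classes")
})

test_that("Fisher index of label-independent features stays near the null", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    y <- rep(0:1, 1000)
    fisher_index(rnorm(2000), y) < 0.02
  }, logical(1))
  expect_gte(sum(hits), 95)
})

test_that("correlation index reproduces the analytic cases", {
  y <- c(0, 1, 0, 1)
  expect_equal(correlation_index(y, y), 1)
  expect_equal(correlation_index(1 - y, y), -1)
  # brute-force oracle value for this 4-point instance (0.98995)
  x <- c(0.1, 0.9, 0.2, 0.8)
  expect_equal(correlation_index(x, y), oracle_corr(x, y),
               tolerance = 1e-12)
  expect_equal(correlation_index(x, y), 0.98995, tolerance = 1e-4)
  expect_warning(r <- correlation_index(rep(1, 4), y), "zero variance")
  expect_equal(r, 0)
})

# n points, half at m - s and half at m + s, with exact sample mean m and
# exact sample variance v
sym_sample <- function(m, v, n) {
  s <- sqrt(v * (n - 1) / n)
  m + c(rep(-s, n / 2), rep(s, n / 2))
}

test_that("t-test index matches hand arithmetic and its sqrt(n) scaling law", {
  x <- c(0, 1, 2, 3); y <- c(0, 0, 1, 1)
  expect_equal(ttest_index(x, y), 2 / sqrt(0.5))
  expect_equal(ttest_index(c(1, 2, 1, 2), y), 0)
  # doubling both classes at identical sample moments scales T by sqrt(2)
  x4 <- c(sym_sample(0.5, 0.5, 4), sym_sample(2.5, 0.5, 4))
  y4 <- rep(c(0, 1), each = 4)
  x8 <- c(sym_sample(0.5, 0.5, 8), sym_sample(2.5, 0.5, 8))
  y8 <- rep(c(0, 1), each = 8)
  expect_equal(ttest_index(x4, y4), 2 / sqrt(0.5 / 4 + 0.5 / 4),
               tolerance = 1e-12)
  expect_equal(ttest_index(x8, y8), sqrt(2) * ttest_index(x4, y4),
               tolerance = 1e-12)
})

test_that("mutual information is 1 bit for an invertible map and ~0 under independence", {
  y <- rep(0:1, 50)
  expect_equal(mutual_information_index(y, y), 1)
  expect_equal(mutual_information_index(1 - y, y), 1)
  expect_equal(mutual_information_index(10 * y - 4, y), 1)
  hits <- vapply(1:40, function(s) {
    set.seed(s)
    yy <- rep(0:1, 2500)
    mutual_information_index(rnorm(5000), yy) < 0.02
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("mutual information is invariant to positive affine maps of x", {
  set.seed(7)
  x <- rnorm(500); y <- rep(0:1, 250)
  base <- mutual_information_index(x, y)
  expect_equal(mutual_information_index(3 * x + 10, y), base,
               tolerance = 1e-12)
})

test_that("MI is symmetric in its two arguments after binning both", {
  set.seed(8)
  x <- rnorm(400)
  y <- rep(0:1, 200)
  expect_equal(mutual_information_index(x, y),
               mutual_information_index(y, x), tolerance = 1e-12)
})

test_that("all four indexes match naive brute-force oracles on random instances", {
  set.seed(9)
  for (i in 1:50) {
    n <- sample(20:200, 1)
    y <- c(rep(0, n %/% 2), rep(1, n - n %/% 2))
    x <- rnorm(n) + sample(0:2, 1) * y
    expect_equal(fisher_index(x, y), oracle_fisher(x, y), tolerance = 1e-9)
    expect_equal(correlation_index(x, y), oracle_corr(x, y),
                 tolerance = 1e-9)
    expect_equal(ttest_index(x, y), oracle_ttest(x, y), tolerance = 1e-9)
    expect_equal(mutual_information_index(x, y), oracle_mi(x, y),
                 tolerance = 1e-9)
  }
})

test_that("Fisher and t statistics are invariant to positive affine transforms", {
  set.seed(10)
  y <- rep(0:1, 100)
  x <- rnorm(200) + y
  for (stat in list(fisher_index, ttest_index)) {
    expect_equal(stat(5 * x + 3, y), stat(x, y), tolerance = 1e-9)
  }
})

test_that("index rescaling maps to [0,1], uses |R|, and degrades gracefully", {
  v <- list(fisher = c(0, 5, 10), corr = c(-0.8, 0.8, 0.1),
            ttest = c(1, 1, 1), mi = c(0.2, 0.1, 0))
  s <- scale_indexes(v)
  expect_equal(unname(s[, "fisher"]), c(0, 0.5, 1))
  expect_equal(s[1, "corr"], s[2, "corr"])     # absolute value first
  expect_equal(unname(s[, "ttest"]), rep(0.5, 3))  # constant -> 0.5
  expect_equal(unname(s[, "mi"]), c(1, 0.5, 0))
  expect_true(all(s >= 0 & s <= 1))
})

test_that("on the planted bench all four indexes rank informative above noise", {
  hits <- vapply(1:100, function(s) {
    b <- generate_feature_bench(2000, 12, 3, effect_size = 2, seed = s)
    fi <- filter_indexes(b$x, b$y)
    all(vapply(list(fi$fisher, abs(fi$corr), fi$ttest, fi$mi), function(v) {
      min(v[b$informative]) > max(v[-b$informative])
    }, logical(1)))
  }, logical(1))
  expect_gte(sum(hits), 95)
})

test_that("index CSV export has the contracted columns", {
  b <- generate_feature_bench(200, 36, 5, 2, seed = 1)
  colnames(b$x) <- feature_names()
  fi <- filter_indexes(b$x, b$y)
  path <- withr::local_tempfile(fileext = ".csv")
  write_indexes_csv(fi, path)
  df <- utils::read.csv(path)
  expect_identical(names(df),
                   c("feature", "fisher", "corr", "ttest", "mi",
                     "fisher01", "corr01", "ttest01", "mi01"))
  expect_equal(nrow(df), 36)
})
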