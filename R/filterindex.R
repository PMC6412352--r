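# Per-feature filter statistics relating one feature vector to the binary
# class label, and their rescaling to the unit interval for fuzzification.

# Sentinel used when a degenerate perfect separator (zero within-class
# variance, distinct means) would otherwise divide by zero; large enough to
# land at 1.0 after min-max rescaling.
INDEX_CAP <- 1e6

check_two_classes <- function(y) {
  if (length(unique(y)) < 2) {
    stop("both classes must be present to compute a filter index",
         call. = FALSE)
  }
}

#' Fisher score of a feature
#'
#' `(mu1 - mu0)^2 / (var1 + var0)` with class-wise sample means and variances
#' (n-1 denominator). When both class variances vanish the score is 0 for
#' equal means and a large cap otherwise (a degenerate perfect separator).
#'
#' @param x Numeric feature vector.
#' @param y Binary labels (0/1), same length.
#' @return Non-negative Fisher score.
#' @export
#' @examples
#' fisher_index(c(0, 1, 2, 3), c(0, 0, 1, 1))  # 4
fisher_index <- function(x, y) {
  check_two_classes(y)
  x0 <- x[y == 0]; x1 <- x[y == 1]
  v0 <- stats::var(x0); v1 <- stats::var(x1)
  dm <- mean(x1) - mean(x0)
  if (v0 + v1 == 0) {
    return(if (dm == 0) 0 else INDEX_CAP)
  }
  dm^2 / (v0 + v1)
}

#' Pearson correlation of a feature with the class label
#'
#' For a binary label this is the point-biserial correlation. The sign is
#' retained here; [scale_indexes()] takes the absolute value before
#' rescaling.
#'
#' @inheritParams fisher_index
#' @return Correlation in `[-1, 1]`; 0 with a warning if either variance is
#'   zero.
#' @export
correlation_index <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance in correlation_index; returning 0")
    return(0)
  }
  stats::cor(x, y)
}

#' Welch t statistic of a feature
#'
#' `|mu1 - mu0| / sqrt(var1/n1 + var0/n0)` with class-wise sample variances.
#' No p-value is computed: the statistic itself is the ranking index.
#'
#' @inheritParams fisher_index
#' @return Non-negative t statistic.
#' @export
ttest_index <- function(x, y) {
  check_two_classes(y)
  x0 <- x[y == 0]; x1 <- x[y == 1]
  if (length(x0) < 2 || length(x1) < 2) {
    stop("each class needs at least 2 observations", call. = FALSE)
  }
  se2 <- stats::var(x1) / length(x1) + stats::var(x0) / length(x0)
  dm <- mean(x1) - mean(x0)
  if (se2 == 0) {
    return(if (dm == 0) 0 else INDEX_CAP)
  }
  abs(dm) / sqrt(se2)
}

#' Plug-in mutual information between a feature and the class label
#'
#' The feature is discretized into `n_bins` equal-width bins over its
#' observed range; the mutual information of the binned joint histogram is
#' returned in bits (log base 2), with empty cells contributing 0.
#'
#' @inheritParams fisher_index
#' @param n_bins Number of equal-width bins (default 10).
#' @return Mutual information in bits, >= 0.
#' @export
mutual_information_index <- function(x, y, n_bins = 10L) {
  check_two_classes(y)
  bx <- discretize_equal_width(x, n_bins)
  by <- if (is.numeric(y) && length(unique(y)) > n_bins) {
    discretize_equal_width(y, n_bins)
  } else {
    match(y, sort(unique(y)))
  }
  joint <- table(bx, by) / length(x)
  px <- rowSums(joint); py <- colSums(joint)
  mi <- 0
  for (i in seq_along(px)) {
    for (j in seq_along(py)) {
      pij <- joint[i, j]
      if (pij > 0) mi <- mi + pij * log2(pij / (px[i] * py[j]))
    }
  }
  max(mi, 0)
}

discretize_equal_width <- function(x, n_bins) {
  rng <- range(x)
  if (rng[2] == rng[1]) return(rep(1L, length(x)))
  findInterval(x, seq(rng[1], rng[2], length.out = n_bins + 1),
               rightmost.closed = TRUE)
}

#' Compute all four filter indexes for every feature
#'
#' @param x Numeric feature matrix (rows = windows, columns = features).
#' @param y Binary labels (0/1).
#' @param mi_bins Bin count for the mutual-information estimator.
#' @return A `filter_index_set`: list with numeric vectors `fisher`, `corr`,
#'   `ttest`, `mi` (one value per feature, named) and the `scaled` matrix
#'   from [scale_indexes()].
#' @export
filter_indexes <- function(x, y, mi_bins = 10L) {
  check_two_classes(y)
  fisher <- apply(x, 2, fisher_index, y = y)
  corr <- suppressWarnings(apply(x, 2, correlation_index, y = y))
  ttest <- apply(x, 2, ttest_index, y = y)
  mi <- apply(x, 2, mutual_information_index, y = y, n_bins = mi_bins)
  out <- list(fisher = fisher, corr = corr, ttest = ttest, mi = mi)
  out$scaled <- scale_indexes(out)
  structure(out, class = "filter_index_set")
}

#' Rescale the four index vectors to the unit interval
#'
#' Per index type: the correlation is replaced by its absolute value, then
#' each index vector is min-max rescaled across the features to `[0, 1]` so
#' the values match the unit domain of the fuzzy membership functions. A
#' constant index vector maps to all 0.5.
#'
#' @param v List with numeric vectors `fisher`, `corr`, `ttest`, `mi`.
#' @return Numeric matrix, features x 4, columns
#'   `c("fisher", "corr", "ttest", "mi")`, values in `[0, 1]`.
#' @export
scale_indexes <- function(v) {
  one <- function(z) {
    rng <- range(z)
    if (rng[2] == rng[1]) return(rep(0.5, length(z)))
    (z - rng[1]) / (rng[2] - rng[1])
  }
  out <- cbind(fisher = one(v$fisher), corr = one(abs(v$corr)),
               ttest = one(v$ttest), mi = one(v$mi))
  rownames(out) <- names(v$fisher)
  out
}

#' Write filter indexes as CSV
#'
#' 36 rows with columns
#' `feature,fisher,corr,ttest,mi,fisher01,corr01,ttest01,mi01`.
#'
#' @param fi A `filter_index_set`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_indexes_csv <- function(fi, path) {
  df <- data.frame(feature = names(fi$fisher),
                   fisher = unname(fi$fisher), corr = unname(fi$corr),
                   ttest = unname(fi$ttest), mi = unname(fi$mi),
                   fisher01 = unname(fi$scaled[, "fisher"]),
                   corr01 = unname(fi$scaled[, "corr"]),
                   ttest01 = unname(fi$scaled[, "ttest"]),
                   mi01 = unname(fi$scaled[, "mi"]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
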