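seg_from <- function(angle, velocity = NULL, fs = 60) {
  if (is.null(velocity)) {
    n <- length(angle)
    velocity <- c(diff(angle), 0) * fs
    velocity[n] <- velocity[n - 1]
  }
  list(angle = angle - mean(angle), velocity = velocity - mean(velocity))
}

test_that("the extractor emits exactly 36 finite, correctly named features", {
  set.seed(1)
  f <- extract_window_features(seg_from(rnorm(180)), fs = 60)
  expect_length(f, 36)
  expect_identical(names(f), feature_names())
  expect_true(all(is.finite(f)))
  expect_identical(feature_names()[1:3], c("I01a", "I02a", "I03a"))
  expect_identical(feature_names()[19], "I01v")
})

test_that("a degenerate all-zero window yields the documented zeros", {
  z <- rep(0, 180)
  f <- extract_window_features(list(angle = z, velocity = z), fs = 60)
  expect_equal(unname(f[c("I01a", "I02a", "I03a", "I04a", "I12a")]),
               rep(0, 5))  # range, SD, energy, ZCR, ShEn
  expect_true(all(is.finite(f)))
})

test_that("ZCR and dominant frequency of a 2 Hz sinusoid are 4/s and 2 Hz", {
  t <- (0:179) / 60
  x <- sin(2 * pi * 2 * t + 0.3)  # phase keeps samples off exact zeros
  f <- extract_window_features(seg_from(x, velocity = x), fs = 60)
  # closed form: a 2 Hz sinusoid crosses zero 4 times per second
  expect_equal(unname(f["I04a"]), 4)
  # direct count oracle
  expect_equal(unname(f["I04a"]), sum(x[-180] * x[-1] < 0) / 3)
  expect_equal(unname(f["I17a"]), 2)  # bin resolution 1/3 Hz, exact bin
})

test_that("Katz fractal dimension of a straight line is 1", {
  for (a in c(0.01, 1, 50)) {
    x <- a * (0:99)
    expect_equal(katz_fd(x), 1, tolerance = 1e-6)
    # brute-force L and d for the line
    L <- sum(sqrt(1 + diff(x)^2))
    d <- max(sqrt((1:99)^2 + (x[-1] - x[1])^2))
    expect_equal(katz_fd(x),
                 log10(99) / (log10(99) + log10(d / L)), tolerance = 1e-12)
  }
})

test_that("quartiles are ordered and interpolated", {
  set.seed(2)
  f <- extract_window_features(seg_from(rnorm(180)), fs = 60)
  expect_lte(f[["I05a"]], f[["I06a"]])
  expect_lte(f[["I06a"]], f[["I07a"]])
  x <- c(1, 2, 3, 4) - 2.5
  f2 <- extract_window_features(
    list(angle = rep(x, 45) - mean(rep(x, 45)),
         velocity = rep(0, 180)), fs = 60)
  expect_equal(unname(f2["I06a"]), 0)
})

test_that("entropy features respect their analytic bounds", {
  set.seed(3)
  for (i in 1:5) {
    f <- extract_window_features(seg_from(rnorm(180)), fs = 60)
    expect_gte(f[["I12a"]], 0)
    expect_lte(f[["I12a"]], log2(16))
    expect_gte(f[["I14a"]], 0)
    expect_lte(f[["I14a"]], log2(91))  # 91 one-sided bins at W = 180
  }
})

test_that("sample entropy orders iid noise above a sinusoid of equal SD", {
  set.seed(4)
  t <- (0:179) / 60
  hits <- vapply(1:50, function(i) {
    noise <- rnorm(180)
    sine <- sin(2 * pi * 2 * t + runif(1, 0, 2 * pi))
    sine <- sine * sd(noise) / sd(sine)
    sample_entropy(noise) > sample_entropy(sine)
  }, logical(1))
  expect_true(all(hits))
})

test_that("sample entropy cap engages for constant and perfectly regular input", {
  x <- rep(3, 50)
  cap <- -log(2 / ((50 - 3) * (50 - 2)))
  expect_equal(sample_entropy(x), cap)
})

test_that("Shannon entropy of a constant window is 0 and of two balanced levels 1", {
  expect_equal(shannon_entropy(rep(5, 100)), 0)
  expect_equal(shannon_entropy(rep(c(0, 1), 50)), 1)
})

test_that("periodogram features match a brute-force DFT oracle on toy windows", {
  set.seed(5)
  for (i in 1:5) {
    x <- rnorm(16); x <- x - mean(x)
    got <- steerwake:::periodogram_hann(x, fs = 8)
    want <- oracle_periodogram(x, fs = 8)
    expect_equal(got$freq, want$freq, tolerance = 1e-12)
    expect_equal(got$psd, want$psd, tolerance = 1e-9)
  }
})

test_that("spectral flux is 0 for a first window and positive on change", {
  set.seed(6)
  a <- seg_from(rnorm(180))
  b <- seg_from(rnorm(180))
  f1 <- extract_window_features(a, fs = 60)
  expect_equal(unname(f1["I15a"]), 0)
  f2 <- extract_window_features(b, fs = 60, prev_mag = attr(f1, "mag"))
  expect_gt(f2[["I15a"]], 0)
  # identical consecutive windows -> zero flux
  f3 <- extract_window_features(a, fs = 60, prev_mag = attr(f1, "mag"))
  expect_equal(unname(f3["I15a"]), 0)
})

test_that("windows with NA or too few samples are rejected", {
  x <- rnorm(180); x[5] <- NA
  expect_error(extract_window_features(seg_from_na <- list(angle = x,
                                                           velocity = rnorm(180)),
                                       60), "NA")
  expect_error(extract_window_features(list(angle = rnorm(4),
                                            velocity = rnorm(4)), 60),
               "too short")
})

test_that("min-max normalizer maps bounds to 0/1, interpolates, clips, and flags constants", {
  x <- cbind(a = c(2, 4, 6), b = c(0, 1, 0.5), c = c(7, 7, 7))
  norm <- fit_normalizer(x)
  expect_equal(unname(norm$lo), c(2, 0, 7))
  expect_equal(unname(norm$hi), c(6, 1, 7))
  expect_identical(unname(norm$constant), c(FALSE, FALSE, TRUE))
  out <- apply_normalizer(c(3, 0.25, 7), norm)
  expect_equal(unname(out), c(0.25, 0.25, 0.5))
  expect_equal(unname(apply_normalizer(c(2, 0, 0), norm))[1], 0)
  expect_equal(unname(apply_normalizer(c(6, 1, 9), norm))[1:2], c(1, 1))
  # clipping of out-of-range test values
  expect_equal(unname(apply_normalizer(c(100, -5, 7), norm))[1:2], c(1, 0))
})

test_that("feature CSV round-trips matrix, names and labels", {
  tr <- generate_trace(scenario_config(duration_s = 30, seed = 9))
  fset <- extract_features(slide_windows(tr, window_spec()), fs = 60)
  path <- withr::local_tempfile(fileext = ".csv")
  write_features_csv(fset, path)
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  expect_identical(header, c(feature_names(), "label"))
  back <- read_features_csv(path)
  expect_equal(back$x, fset$x, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(back$y, fset$y)
})
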