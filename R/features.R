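# Per-window feature extraction: 18 features per channel (angle, velocity),
# 12 in the time domain and 6 from the one-sided Hann periodogram.

#' Names of the 36 window features
#'
#' `I01a..I18a` are computed from the steering-angle channel, `I01v..I18v`
#' from the steering-velocity channel. Per channel, in order: range, standard
#' deviation, energy, zero-crossing rate, first/second/third quartile, Katz
#' fractal dimension, skewness, kurtosis, sample entropy, Shannon entropy,
#' spectral variance, spectral entropy, spectral flux, spectral centroid
#' (centre of gravity of frequency), dominant frequency, mean power spectral
#' density.
#'
#' @return Character vector of length 36.
#' @export
feature_names <- function() {
  idx <- sprintf("I%02d", 1:18)
  c(paste0(idx, "a"), paste0(idx, "v"))
}

#' Extract the 36 features of one window
#'
#' Computes, per channel, 12 time-domain features and 6 frequency-domain
#' features from the one-sided periodogram of the detrended window with a
#' Hann taper. Conventions are fixed as follows: ZCR counts strict sign
#' products `x_k * x_{k+1} < 0` per second of window duration; quartiles use
#' linear interpolation; Katz fractal dimension uses unit-index abscissa;
#' skewness is `m3 / m2^{3/2}` and kurtosis the non-excess `m4 / m2^2`;
#' sample entropy uses `m = 2`, `r = 0.2 * SD`, Chebyshev distance and no
#' self-matches, capped at `-ln(2 / ((W-m-1)(W-m)))` when no matches resolve;
#' Shannon entropy uses a 16-bin equal-width histogram of the window with
#' `0 log 0 := 0`. Spectral flux is the squared difference of the
#' L1-normalised magnitude spectrum against the previous window of the same
#' recording and channel (0 for a recording's first window); the dominant
#' frequency excludes the DC bin.
#'
#' @param seg A `window_segment` from [slide_windows()], or any list with
#'   numeric `angle` and `velocity` vectors of length >= 8.
#' @param fs Sampling rate, Hz.
#' @param prev_mag Optional list with elements `angle` and `velocity`: the
#'   previous window's L1-normalised magnitude spectra, as returned in the
#'   `mag` attribute of this function's result. `NULL` marks the first window
#'   of a recording (flux = 0).
#' @return Named numeric vector of length 36 (`I01a..I18a, I01v..I18v`), with
#'   attribute `mag` carrying this window's normalised magnitude spectra for
#'   the next flux computation.
#' @export
extract_window_features <- function(seg, fs, prev_mag = NULL) {
  if (anyNA(seg$angle) || anyNA(seg$velocity)) {
    stop("window contains NA samples", call. = FALSE)
  }
  if (length(seg$angle) < 8L) {
    stop("window too short: entropy estimators need at least 8 samples",
         call. = FALSE)
  }
  fa <- channel_features(seg$angle, fs, prev_mag$angle)
  fv <- channel_features(seg$velocity, fs, prev_mag$velocity)
  out <- c(fa$values, fv$values)
  names(out) <- feature_names()
  attr(out, "mag") <- list(angle = fa$mag, velocity = fv$mag)
  out
}

channel_features <- function(x, fs, prev_mag = NULL) {
  n <- length(x)
  dur <- n / fs
  m2 <- mean((x - mean(x))^2)
  time_feats <- c(
    range = max(x) - min(x),
    sd = stats::sd(x),
    energy = sum(x^2),
    zcr = sum(x[-n] * x[-1] < 0) / dur,
    q1 = unname(stats::quantile(x, 0.25)),
    q2 = unname(stats::quantile(x, 0.50)),
    q3 = unname(stats::quantile(x, 0.75)),
    kfd = katz_fd(x),
    skewness = if (m2 > 0) mean((x - mean(x))^3) / m2^1.5 else 0,
    kurtosis = if (m2 > 0) mean((x - mean(x))^4) / m2^2 else 0,
    sampen = sample_entropy(x),
    shen = shannon_entropy(x)
  )
  sp <- periodogram_hann(x, fs)
  freq_feats <- spectral_features(sp, prev_mag)
  list(values = c(time_feats, freq_feats$values), mag = freq_feats$mag)
}

#' Katz fractal dimension of a sample path
#'
#' `log10(n-1) / (log10(n-1) + log10(d/L))` with path length
#' `L = sum sqrt(1 + diff(x)^2)` and maximal excursion
#' `d = max_k sqrt(k^2 + (x_k - x_0)^2)` over the unit-index abscissa.
#' A straight line has dimension exactly 1.
#'
#' @param x Numeric vector, length >= 3.
#' @return Katz fractal dimension (>= 1 for non-degenerate paths).
#' @export
katz_fd <- function(x) {
  n <- length(x)
  dx <- diff(x)
  L <- sum(sqrt(1 + dx^2))
  k <- seq_len(n - 1)
  d <- max(sqrt(k^2 + (x[-1] - x[1])^2))
  if (L == 0 || d == 0) return(1)
  log10(n - 1) / (log10(n - 1) + log10(d / L))
}

#' Sample entropy
#'
#' SampEn(m, r) is the negative log conditional probability that two
#' subsequences matching for `m` points (Chebyshev distance within `r`,
#' self-matches excluded) still match at `m + 1` points. Lower values mean a
#' more regular signal; drowsy steering (slow drift, rare jerks) is more
#' regular than awake micro-correction noise.
#'
#' When either count is zero (including constant windows, where `r = 0`), the
#' maximum resolvable value `-ln(2 / ((n-m-1)(n-m)))` is returned so that the
#' ordering of windows is preserved without infinities.
#'
#' @param x Numeric vector.
#' @param m Embedding dimension (default 2).
#' @param r Tolerance; default `0.2 * sd(x)`.
#' @return Sample entropy in nats.
#' @export
sample_entropy <- function(x, m = 2L, r = 0.2 * stats::sd(x)) {
  n <- length(x)
  cap <- -log(2 / ((n - m - 1) * (n - m)))
  if (!is.finite(r) || r <= 0) return(cap)
  D <- abs(outer(x, x, "-"))
  idx <- seq_len(n - m)
  Dm <- D[idx, idx, drop = FALSE]
  for (j in seq_len(m - 1)) {
    Dm <- pmax(Dm, D[idx + j, idx + j, drop = FALSE])
  }
  up <- upper.tri(Dm)
  B <- sum(Dm[up] <= r)
  Dm1 <- pmax(Dm, D[idx + m, idx + m, drop = FALSE])
  A <- sum(Dm1[up] <= r)
  if (A == 0 || B == 0) return(cap)
  -log(A / B)
}

#' Shannon entropy of a window's amplitude histogram
#'
#' Equal-width histogram with `bins` cells over the window's observed range;
#' entropy in bits with `0 log 0 := 0`. A constant window has entropy 0.
#'
#' @param x Numeric vector.
#' @param bins Number of histogram bins (default 16).
#' @return Entropy in bits, in `[0, log2(bins)]`.
#' @export
shannon_entropy <- function(x, bins = 16L) {
  rng <- range(x)
  if (rng[2] == rng[1]) return(0)
  cell <- findInterval(x, seq(rng[1], rng[2], length.out = bins + 1),
                       rightmost.closed = TRUE)
  p <- tabulate(cell, nbins = bins) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# One-sided periodogram of a mean-removed window with a Hann taper.
# Returns freq (Hz), psd (power/Hz) and the L1-normalised magnitude
# spectrum used by spectral flux.
periodogram_hann <- function(x, fs) {
  n <- length(x)
  h <- 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))
  X <- stats::fft(x * h)
  nf <- n %/% 2 + 1
  mag <- Mod(X[seq_len(nf)])
  # one-sided PSD: double interior bins, normalise by taper power
  scale <- fs * sum(h^2)
  psd <- mag^2 / scale
  if (n %% 2 == 0) {
    psd[2:(nf - 1)] <- 2 * psd[2:(nf - 1)]
  } else {
    psd[2:nf] <- 2 * psd[2:nf]
  }
  s <- sum(mag)
  list(freq = (seq_len(nf) - 1) * fs / n, psd = psd,
       mag_l1 = if (s > 0) mag / s else mag)
}

spectral_features <- function(sp, prev_mag = NULL) {
  tot <- sum(sp$psd)
  if (tot > 0) {
    p <- sp$psd / tot
    cgf <- sum(sp$freq * p)
    spec_var <- sum(p * (sp$freq - cgf)^2)
    pp <- p[p > 0]
    spec_ent <- -sum(pp * log2(pp))
    dom <- sp$freq[-1][which.max(sp$psd[-1])]  # DC bin excluded
  } else {
    cgf <- 0; spec_var <- 0; spec_ent <- 0; dom <- 0
  }
  flux <- if (is.null(prev_mag)) 0 else sum((sp$mag_l1 - prev_mag)^2)
  list(values = c(spec_var = spec_var, spec_entropy = spec_ent, flux = flux,
                  cgf = cgf, dom_freq = dom, mean_psd = mean(sp$psd)),
       mag = sp$mag_l1)
}

#' Build the feature matrix for a sequence of windows
#'
#' Runs [extract_window_features()] over the windows of one recording in
#' order, threading the previous window's magnitude spectrum through so that
#' spectral flux is well defined, then drops windows whose label is `NA`
#' (KSS 7).
#'
#' @param windows List of `window_segment`s from [slide_windows()].
#' @param fs Sampling rate, Hz.
#' @param keep_dropped Keep KSS-7 windows (with `NA` label) in the output?
#'   Default `FALSE`.
#' @return A `feature_set`: list with `x` (numeric matrix, one row per kept
#'   window, 36 named columns), `y` (integer labels 0/1, `NA` only if
#'   `keep_dropped`), and `start_sample` (0-based window starts).
#' @export
extract_features <- function(windows, fs, keep_dropped = FALSE) {
  if (length(windows) == 0) {
    x <- matrix(numeric(0), 0, 36, dimnames = list(NULL, feature_names()))
    return(structure(list(x = x, y = integer(0), start_sample = integer(0)),
                     class = "feature_set"))
  }
  prev <- NULL
  rows <- vector("list", length(windows))
  for (i in seq_along(windows)) {
    f <- extract_window_features(windows[[i]], fs, prev)
    prev <- attr(f, "mag")
    rows[[i]] <- as.numeric(f)
  }
  x <- do.call(rbind, rows)
  colnames(x) <- feature_names()
  y <- vapply(windows, function(w) as.integer(w$label), integer(1))
  start <- vapply(windows, function(w) as.integer(w$start_sample), integer(1))
  if (!keep_dropped) {
    keep <- !is.na(y)
    x <- x[keep, , drop = FALSE]
    y <- y[keep]
    start <- start[keep]
  }
  structure(list(x = x, y = y, start_sample = start), class = "feature_set")
}

#' Min-max normalizer over training windows
#'
#' `fit_normalizer` records the per-feature training minimum and maximum;
#' `apply_normalizer` rescales to `(x - lo) / (hi - lo)` and clips to
#' `[0, 1]` (test-time values may exceed the training bounds). A constant
#' training feature is flagged and maps to 0.5 so the fuzzifier input stays
#' defined.
#'
#' @param x Numeric matrix of training features (rows = windows).
#' @return `fit_normalizer`: list with `lo`, `hi` and logical `constant`;
#'   `apply_normalizer`: matrix (or vector) of the same shape as its input
#'   with values in `[0, 1]`.
#' @export
fit_normalizer <- function(x) {
  stopifnot(nrow(x) >= 2)
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  structure(list(lo = lo, hi = hi, constant = hi == lo),
            class = "feature_normalizer")
}

#' @rdname fit_normalizer
#' @param norm A fitted `feature_normalizer`.
#' @export
apply_normalizer <- function(x, norm) {
  stopifnot(inherits(norm, "feature_normalizer"))
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, 1)
  out <- sweep(x, 2, norm$lo)
  span <- norm$hi - norm$lo
  span[norm$constant] <- 1
  out <- sweep(out, 2, span, "/")
  out[, norm$constant] <- 0.5
  out <- pmin(pmax(out, 0), 1)
  if (vec) out <- drop(out)
  out
}

#' Write / read a feature matrix as CSV
#'
#' Rows are windows; columns are the 36 named features plus `label`.
#'
#' @param fset A `feature_set`.
#' @param path File path.
#' @return `write_features_csv` returns `path` invisibly; `read_features_csv`
#'   returns a `feature_set`.
#' @export
write_features_csv <- function(fset, path) {
  df <- as.data.frame(fset$x)
  df$label <- fset$y
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"label" %in% names(df)) stop("feature CSV lacks a label column",
                                    call. = FALSE)
  nm <- setdiff(names(df), "label")
  if (!identical(nm, feature_names())) {
    if (!all(feature_names() %in% nm)) {
      stop("feature CSV does not contain the 36 expected feature columns",
           call. = FALSE)
    }
    nm <- feature_names()
  }
  structure(list(x = as.matrix(df[, nm]), y = as.integer(df$label),
                 start_sample = integer(0)),
            class = "feature_set")
}
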