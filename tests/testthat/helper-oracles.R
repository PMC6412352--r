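# Independent brute-force oracles. These deliberately use naive loops and
# textbook formulas, sharing no code with the package implementation.

oracle_fisher <- function(x, y) {
  x0 <- x[y == 0]; x1 <- x[y == 1]
  m0 <- sum(x0) / length(x0); m1 <- sum(x1) / length(x1)
  v0 <- sum((x0 - m0)^2) / (length(x0) - 1)
  v1 <- sum((x1 - m1)^2) / (length(x1) - 1)
  if (v0 + v1 == 0) return(if (m1 == m0) 0 else 1e6)
  (m1 - m0)^2 / (v0 + v1)
}

oracle_corr <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx <- dx + (x[i] - mx)^2
    dy <- dy + (y[i] - my)^2
  }
  num / sqrt(dx * dy)
}

oracle_ttest <- function(x, y) {
  x0 <- x[y == 0]; x1 <- x[y == 1]
  m0 <- mean(x0); m1 <- mean(x1)
  se2 <- var(x1) / length(x1) + var(x0) / length(x0)
  if (se2 == 0) return(if (m1 == m0) 0 else 1e6)
  abs(m1 - m0) / sqrt(se2)
}

oracle_mi <- function(x, y, n_bins = 10L) {
  rng <- range(x)
  if (rng[2] == rng[1]) bx <- rep(1L, length(x)) else {
    edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
    bx <- vapply(x, function(v) {
      b <- max(which(v >= edges[-length(edges)]))
      min(b, n_bins)
    }, integer(1))
  }
  ys <- sort(unique(y))
  n <- length(x)
  mi <- 0
  for (i in seq_len(n_bins)) {
    for (j in seq_along(ys)) {
      pij <- sum(bx == i & y == ys[j]) / n
      if (pij > 0) {
        pi_ <- sum(bx == i) / n
        pj_ <- sum(y == ys[j]) / n
        mi <- mi + pij * log2(pij / (pi_ * pj_))
      }
    }
  }
  mi
}

# Naive 81-rule Takagi-Sugeno evaluation: explicit triple loop over the
# lexicographic (F, R, T, I) rule order with L < M < H.
oracle_importance <- function(h, cmat, smat, alpha) {
  h <- pmin(pmax(h, 0), 1)
  num <- 0; den <- 0
  l <- 0
  for (a1 in 1:3) for (a2 in 1:3) for (a3 in 1:3) for (a4 in 1:3) {
    l <- l + 1
    lv <- c(a1, a2, a3, a4)
    w <- 1
    for (j in 1:4) {
      w <- w * exp(-0.5 * ((h[j] - cmat[j, lv[j]]) / smat[j, lv[j]])^2)
    }
    num <- num + w * alpha[l]
    den <- den + w
  }
  num / den
}

# Brute-force one-sided Hann periodogram via the DFT definition.
oracle_periodogram <- function(x, fs) {
  n <- length(x)
  h <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
  xw <- x * h
  nf <- n %/% 2 + 1
  psd <- numeric(nf)
  for (k in seq_len(nf) - 1) {
    re <- 0; im <- 0
    for (t in seq_len(n) - 1) {
      re <- re + xw[t + 1] * cos(2 * pi * k * t / n)
      im <- im - xw[t + 1] * sin(2 * pi * k * t / n)
    }
    psd[k + 1] <- (re^2 + im^2) / (fs * sum(h^2))
  }
  if (n %% 2 == 0) psd[2:(nf - 1)] <- 2 * psd[2:(nf - 1)]
  else psd[2:nf] <- 2 * psd[2:nf]
  list(freq = (seq_len(nf) - 1) * fs / n, psd = psd)
}

# AUC as the Mann-Whitney U statistic over all positive/negative pairs.
oracle_auc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  u <- 0
  for (p in pos) for (q in neg) {
    u <- u + (p > q) + 0.5 * (p == q)
  }
  u / (length(pos) * length(neg))
}

random_fuzzy_params <- function() {
  cmat <- t(apply(matrix(runif(12), 4, 3), 1, sort))
  smat <- matrix(runif(12, 0.05, 1), 4, 3)
  alpha <- sample(c(0, 0.5, 1), 81, replace = TRUE)
  list(cmat = cmat, smat = smat, alpha = alpha,
       params = fuzzy_params(cmat, smat, alpha))
}
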