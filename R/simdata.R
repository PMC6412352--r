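# Synthetic steering-behaviour generator.
#
# No public driving-simulator corpus with per-sample KSS annotation exists,
# so the package ships a generator that plants the two behavioural regimes
# reported throughout the drowsiness literature: awake lane keeping is a
# stream of frequent small corrections around the track line (high
# zero-crossing rate after detrending), while drowsy steering alternates slow
# lateral drift with sparse large corrective jerks (sawtooth-like, low ZCR,
# high amplitude).

#' Scenario configuration for the synthetic steering generator
#'
#' Describes a simulated drive: a sinusoidal curved track, an awake
#' correction process, a drowsy drift-and-correct process, measurement noise,
#' and a monotone Karolinska Sleepiness Scale (KSS) profile that switches the
#' regimes.
#'
#' @param duration_s Drive duration in seconds.
#' @param fs Sampling rate in Hz. `duration_s * fs` must be a whole number of
#'   samples.
#' @param track_curve_amp Amplitude of the road-curvature component of the
#'   steering angle, degrees.
#' @param track_curve_period_s Period of the sinusoidal track curvature,
#'   seconds.
#' @param awake_correction_rate Poisson rate of small lane-keeping
#'   corrections while awake, corrections per second.
#' @param awake_correction_amp Typical magnitude of an awake correction,
#'   degrees.
#' @param drowsy_correction_rate Poisson rate of large corrective jerks while
#'   drowsy, corrections per second. Must be below `awake_correction_rate`.
#' @param drowsy_correction_amp Typical magnitude of a drowsy corrective
#'   jerk, degrees. Must exceed `awake_correction_amp`.
#' @param drift_rate Magnitude of the slow drowsy drift, degrees per second.
#' @param noise_sd Standard deviation of additive Gaussian measurement noise,
#'   degrees.
#' @param kss_profile Data frame with columns `time` (seconds, starting at 0,
#'   strictly increasing) and `kss` (integers 1-9, non-decreasing); each row
#'   sets the KSS value from `time` onwards. `NULL` gives an even ramp
#'   through all nine levels over the drive.
#' @param seed Integer seed; fixes the generated trace bit-for-bit.
#'
#' @return An object of class `scenario_config`.
#' @seealso [generate_trace()]
#' @export
scenario_config <- function(duration_s = 300,
                            fs = 60,
                            track_curve_amp = 20,
                            track_curve_period_s = 30,
                            awake_correction_rate = 4,
                            awake_correction_amp = 0.5,
                            drowsy_correction_rate = 0.25,
                            drowsy_correction_amp = 8,
                            drift_rate = 2,
                            noise_sd = 0.1,
                            kss_profile = NULL,
                            seed = 1L) {
  if (!is.numeric(duration_s) || length(duration_s) != 1 || duration_s <= 0) {
    stop("invalid scenario config: duration_s must be a positive number",
         call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("invalid scenario config: fs must be a positive number", call. = FALSE)
  }
  n <- duration_s * fs
  if (abs(n - round(n)) > 1e-9) {
    stop("invalid scenario config: duration_s * fs must be an integer ",
         "number of samples", call. = FALSE)
  }
  if (drowsy_correction_rate >= awake_correction_rate) {
    stop("invalid scenario config: drowsy_correction_rate must be below ",
         "awake_correction_rate", call. = FALSE)
  }
  if (drowsy_correction_amp <= awake_correction_amp) {
    stop("invalid scenario config: drowsy_correction_amp must exceed ",
         "awake_correction_amp", call. = FALSE)
  }
  if (is.null(kss_profile)) {
    kss_profile <- data.frame(time = seq(0, duration_s, length.out = 10)[1:9],
                              kss = 1:9)
  }
  stopifnot(is.data.frame(kss_profile),
            all(c("time", "kss") %in% names(kss_profile)))
  if (any(diff(kss_profile$time) <= 0) || kss_profile$time[1] < 0) {
    stop("invalid scenario config: kss_profile times must start at >= 0 and ",
         "strictly increase", call. = FALSE)
  }
  if (any(diff(kss_profile$kss) < 0)) {
    stop("invalid scenario config: kss_profile must be non-decreasing",
         call. = FALSE)
  }
  if (!all(kss_profile$kss %in% 1:9)) {
    stop("invalid scenario config: kss values must be integers 1..9",
         call. = FALSE)
  }
  structure(list(duration_s = duration_s, fs = fs,
                 track_curve_amp = track_curve_amp,
                 track_curve_period_s = track_curve_period_s,
                 awake_correction_rate = awake_correction_rate,
                 awake_correction_amp = awake_correction_amp,
                 drowsy_correction_rate = drowsy_correction_rate,
                 drowsy_correction_amp = drowsy_correction_amp,
                 drift_rate = drift_rate, noise_sd = noise_sd,
                 kss_profile = kss_profile, seed = as.integer(seed)),
            class = "scenario_config")
}

# Evaluate the KSS step profile on a time grid.
kss_at <- function(profile, t) {
  idx <- findInterval(t, profile$time)
  idx[idx < 1] <- 1L
  as.integer(profile$kss[idx])
}

#' Generate a synthetic steering trace
#'
#' Simulates a steering-wheel angle recording as the sum of a sinusoidal
#' track-curvature component, a regime-dependent correction process, and
#' Gaussian noise. While the KSS profile is at 8 or 9 the drowsy regime is
#' active: the wheel drifts linearly at `drift_rate` (random sign) and
#' Poisson-timed corrective jerks of roughly `drowsy_correction_amp` snap it
#' back towards the track line. At KSS 1-6 (and at the transitional KSS 7,
#' whose windows are discarded downstream anyway) the awake regime applies:
#' Poisson-timed small corrections of magnitude `awake_correction_amp` that
#' relax exponentially, producing frequent zero crossings about the track
#' line. The velocity channel is the first-order forward difference of the
#' angle scaled by `fs` (last sample repeated to keep equal length).
#'
#' The generator is fully deterministic under `cfg$seed`.
#'
#' @param cfg A [scenario_config()].
#' @return A `steer_trace`: data frame with columns `time` (s), `angle`
#'   (deg), `velocity` (deg/s) and `kss` (integer 1-9), with the sampling
#'   rate in attribute `fs`.
#' @export
#' @examples
#' tr <- generate_trace(scenario_config(duration_s = 60, seed = 7))
#' str(tr)
generate_trace <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  n <- as.integer(round(cfg$duration_s * cfg$fs))
  t <- (seq_len(n) - 1) / cfg$fs
  kss <- kss_at(cfg$kss_profile, t)
  drowsy <- kss >= 8

  local_seed(cfg$seed)
  track <- cfg$track_curve_amp * sin(2 * pi * t / cfg$track_curve_period_s)

  dt <- 1 / cfg$fs
  dev <- numeric(n)          # deviation from the track line
  relax <- exp(-dt / 0.5)    # awake corrections relax with tau = 0.5 s
  drift_sign <- sample(c(-1, 1), 1)
  # Poisson thinning: draw one uniform per sample, compare to the regime rate
  u <- stats::runif(n)
  awake_hits <- u < cfg$awake_correction_rate * dt
  drowsy_hits <- u < cfg$drowsy_correction_rate * dt
  awake_kick <- stats::rnorm(n, 0, cfg$awake_correction_amp)
  jerk_frac <- stats::runif(n, 0.8, 1.2)  # jerk overshoot/undershoot

  d_prev <- 0
  for (k in seq_len(n)) {
    if (drowsy[k]) {
      d <- d_prev + drift_sign * cfg$drift_rate * dt
      if (drowsy_hits[k] || abs(d) > cfg$drowsy_correction_amp) {
        # large corrective jerk back across the track line
        d <- d - sign(d) * min(abs(d) * jerk_frac[k], cfg$drowsy_correction_amp)
        drift_sign <- sample(c(-1, 1), 1)
      }
    } else {
      d <- d_prev * relax
      if (awake_hits[k]) d <- d + awake_kick[k]
    }
    dev[k] <- d
    d_prev <- d
  }

  angle <- track + dev + stats::rnorm(n, 0, cfg$noise_sd)
  velocity <- c(diff(angle), 0) * cfg$fs
  velocity[n] <- velocity[n - 1]

  structure(data.frame(time = t, angle = angle, velocity = velocity,
                       kss = kss),
            fs = cfg$fs, class = c("steer_trace", "data.frame"))
}

#' Generate an abstract feature bench with planted informative columns
#'
#' Builds a feature matrix with balanced binary labels in which
#' `n_informative` columns are shifted by `effect_size` in class 1 while the
#' remaining columns are label-independent standard normal noise. All columns
#' are then min-max scaled to `[0, 1]`. Used to test selectors in isolation
#' from the signal-processing stages.
#'
#' @param n_samples Number of rows (windows). Made even internally so classes
#'   balance exactly.
#' @param n_features Number of feature columns.
#' @param n_informative Number of planted informative columns (the first
#'   `n_informative` after an internal shuffle; indices are returned).
#' @param effect_size Mean shift of informative columns in class 1, in
#'   within-class standard deviations.
#' @param seed Integer seed.
#' @return List with `x` (numeric matrix `n_samples x n_features`, columns
#'   named `V1..`), `y` (integer 0/1 vector), `informative` (column indices
#'   of the planted features).
#' @export
generate_feature_bench <- function(n_samples, n_features, n_informative,
                                   effect_size, seed = 1L) {
  if (n_informative > n_features) {
    stop("n_informative must not exceed n_features", call. = FALSE)
  }
  n_samples <- 2L * (as.integer(n_samples) %/% 2L)
  local_seed(seed)
  y <- rep(c(0L, 1L), n_samples / 2)
  x <- matrix(stats::rnorm(n_samples * n_features), n_samples, n_features)
  informative <- sort(sample.int(n_features, n_informative))
  for (j in informative) x[, j] <- x[, j] + effect_size * y
  x <- apply(x, 2, function(col) {
    rng <- range(col)
    if (rng[2] > rng[1]) (col - rng[1]) / (rng[2] - rng[1]) else rep(0.5, length(col))
  })
  colnames(x) <- paste0("V", seq_len(n_features))
  list(x = x, y = y, informative = informative)
}

#' Write / read a steering trace as CSV
#'
#' Round-trips the `time,angle,velocity,kss` dialect exactly to 9 significant
#' digits.
#'
#' @param trace A `steer_trace`.
#' @param path File path.
#' @param fs Sampling rate to attach when reading; inferred from the time
#'   column when `NULL`.
#' @return `write_trace_csv` returns `path` invisibly; `read_trace_csv`
#'   returns a `steer_trace`.
#' @export
write_trace_csv <- function(trace, path) {
  df <- as.data.frame(trace)
  df$time <- signif(df$time, 9)
  df$angle <- signif(df$angle, 9)
  df$velocity <- signif(df$velocity, 9)
  utils::write.csv(df[, c("time", "angle", "velocity", "kss")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path, fs = NULL) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time", "angle", "kss") %in% names(df)))
  if (is.null(df$velocity)) {
    if (is.null(fs)) fs <- infer_fs(df$time)
    df$velocity <- c(diff(df$angle), 0) * fs
    n <- nrow(df)
    if (n > 1) df$velocity[n] <- df$velocity[n - 1]
  }
  if (is.null(fs)) fs <- infer_fs(df$time)
  if (!all(df$kss %in% 1:9)) {
    stop("invalid KSS labels in trace file: values must be in 1..9",
         call. = FALSE)
  }
  structure(df[, c("time", "angle", "velocity", "kss")], fs = fs,
            class = c("steer_trace", "data.frame"))
}

infer_fs <- function(t) {
  dt <- diff(t)
  if (length(dt) == 0 || any(dt <= 0)) {
    stop("time column must be strictly increasing", call. = FALSE)
  }
  1 / stats::median(dt)
}

# Seed the RNG locally, restoring the caller's RNG state when the calling
# function exits.
local_seed <- function(seed, env = parent.frame()) {
  has_seed <- exists(".Random.seed", globalenv(), inherits = FALSE)
  restore <- if (has_seed) {
    bquote(assign(".Random.seed", .(get(".Random.seed", globalenv())),
                  envir = globalenv()))
  } else {
    quote(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  do.call(on.exit, list(restore, add = TRUE), envir = env)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  invisible(NULL)
}
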