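# Windowing, road-curvature removal and KSS binarization.

#' Sliding-window specification
#'
#' The analysis unit is a 3-second sliding window (180 samples at 60 Hz) with
#' 50% overlap (90 samples). Each channel is detrended within the window by
#' subtracting its own window mean, which removes the slowly varying road
#' curvature component and leaves the driver's corrective activity.
#'
#' @param length_samples Window length W in samples (default 180).
#' @param overlap_samples Overlap between successive windows in samples
#'   (default 90); must satisfy `0 <= overlap < length`.
#' @param fs Sampling rate, Hz.
#' @return A `window_spec` object.
#' @export
window_spec <- function(length_samples = 180L, overlap_samples = 90L,
                        fs = 60) {
  length_samples <- as.integer(length_samples)
  overlap_samples <- as.integer(overlap_samples)
  if (overlap_samples < 0L || overlap_samples >= length_samples) {
    stop("window_spec requires 0 <= overlap_samples < length_samples",
         call. = FALSE)
  }
  structure(list(length_samples = length_samples,
                 overlap_samples = overlap_samples, fs = fs),
            class = "window_spec")
}

#' Resolve a window specification given in seconds
#'
#' Configuration files give `window.length_s` (default 3.0) and
#' `window.overlap_frac` (default 0.5); both are resolved to whole samples at
#' the trace's sampling rate, with an exact-integer check.
#'
#' @param length_s Window length in seconds.
#' @param overlap_frac Overlap as a fraction of the window length.
#' @param fs Sampling rate, Hz.
#' @return A [window_spec()].
#' @export
window_spec_seconds <- function(length_s = 3.0, overlap_frac = 0.5, fs = 60) {
  w <- length_s * fs
  ov <- overlap_frac * w
  if (abs(w - round(w)) > 1e-9 || abs(ov - round(ov)) > 1e-9) {
    stop("window length and overlap must resolve to whole samples at fs = ",
         fs, call. = FALSE)
  }
  window_spec(round(w), round(ov), fs)
}

#' Cut a trace into detrended, labelled windows
#'
#' Windows start at sample 0 and advance by `length - overlap` samples
#' (0-based, half-open `[start, start + W)`); trailing samples that do not
#' fill a window are discarded. Within each window every channel is detrended
#' by subtracting its own window mean. The window label is the binarized KSS
#' at the window's centre sample: 1-6 awake (0), 8-9 drowsy (1), 7 dropped
#' (`NA`).
#'
#' @param trace A `steer_trace` (see [generate_trace()], [read_trace_csv()]).
#' @param spec A [window_spec()].
#' @return List of `window_segment`s, each a list with `index`,
#'   `start_sample` (0-based), `angle` and `velocity` (detrended numeric
#'   vectors of length W), `kss_center`, and `label` (0, 1 or `NA` for
#'   dropped). A trace shorter than one window yields an empty list with a
#'   warning.
#' @export
slide_windows <- function(trace, spec) {
  stopifnot(inherits(spec, "window_spec"))
  w <- spec$length_samples
  step <- w - spec$overlap_samples
  n <- nrow(trace)
  if (n < w) {
    warning("trace shorter than one window; no windows emitted")
    return(list())
  }
  starts <- seq.int(0L, n - w, by = step)
  lapply(seq_along(starts), function(i) {
    s <- starts[i]
    idx <- (s + 1L):(s + w)
    ang <- trace$angle[idx]
    vel <- trace$velocity[idx]
    center_kss <- trace$kss[s + (w + 1L) %/% 2L]
    list(index = i, start_sample = s,
         angle = ang - mean(ang),
         velocity = vel - mean(vel),
         kss_center = center_kss,
         label = binarize_kss(center_kss))
  })
}

#' Binarize KSS values
#'
#' KSS 1-6 map to the awake class (0), 8-9 to the drowsy class (1), and 7 —
#' the transitional level — is dropped (`NA`) so that the two classes stay
#' well separated.
#'
#' @param kss Integer vector of KSS values in 1..9.
#' @return Integer vector: 0 (awake), 1 (drowsy) or `NA` (dropped).
#' @export
#' @examples
#' binarize_kss(c(1, 6, 7, 8, 9))
binarize_kss <- function(kss) {
  if (any(!kss %in% 1:9)) {
    stop("invalid KSS label: values must be integers in 1..9", call. = FALSE)
  }
  out <- integer(length(kss))
  out[kss <= 6] <- 0L
  out[kss >= 8] <- 1L
  out[kss == 7] <- NA_integer_
  out
}
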