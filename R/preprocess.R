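# Denoising and segmentation: zero-phase notch + Butterworth bandpass,
# then labeled overlapping windows cut inside annotated movement intervals.

#' Zero-phase powerline notch filter
#'
#' Applies a second-order IIR notch at `f0` forward and backward (zero phase)
#' to every channel.  The -3 dB notch width is `f0 / q`.
#'
#' @param signal Channel matrix (`n_channels x n_samples`) or an
#'   `emg_recording` (filtered in place, annotations kept).
#' @param fs Sampling rate in Hz (ignored for recordings).
#' @param f0 Notch frequency in Hz, default 50 (European powerline).
#' @param q Quality factor; 30 gives a ~1.7 Hz notch at 50 Hz.
#' @return Same type as `signal`, same shape.
#' @export
notch_filter <- function(signal, fs = NULL, f0 = 50, q = 30) {
  if (inherits(signal, "emg_recording")) {
    signal$signal <- notch_filter(signal$signal, signal$fs, f0, q)
    return(signal)
  }
  if (is.null(fs)) stop_emg("fs is required for a bare matrix",
                            "emg_parameter_error")
  if (f0 <= 0 || f0 >= fs / 2) {
    stop_emg("notch frequency must satisfy 0 < f0 < fs/2",
             "emg_parameter_error")
  }
  apply_zero_phase(notch_design(f0, fs, q), signal)
}

#' Zero-phase Butterworth bandpass filter
#'
#' Fourth-order (prototype) Butterworth bandpass applied forward and backward;
#' removes DC and out-of-band noise without phase distortion, so zero-crossing
#' and slope-sign counts downstream are not shifted.
#'
#' @inheritParams notch_filter
#' @param low,high Band edges in Hz.
#' @param order Butterworth prototype order.
#' @return Same type as `signal`, same shape.
#' @export
bandpass_filter <- function(signal, fs = NULL, low = 20, high = 500,
                            order = 4) {
  if (inherits(signal, "emg_recording")) {
    signal$signal <- bandpass_filter(signal$signal, signal$fs, low, high, order)
    return(signal)
  }
  if (is.null(fs)) stop_emg("fs is required for a bare matrix",
                            "emg_parameter_error")
  if (!(0 < low && low < high && high < fs / 2)) {
    stop_emg("band must satisfy 0 < low < high < fs/2", "emg_parameter_error")
  }
  apply_zero_phase(butter_design(order, c(low, high) / (fs / 2), "pass"),
                   signal)
}

#' Cut labeled overlapping windows from annotated movement intervals
#'
#' Every annotated movement interval of length `T` samples yields
#' `floor((T - W) / step) + 1` windows of `W = round(window_ms * fs / 1000)`
#' samples, starting `step = W * (1 - overlap_fraction)` samples apart.
#' Windows never cross interval boundaries and rest periods are never
#' windowed (rest is not one of the movement classes).  Intervals shorter than
#' one window are skipped with a warning.
#'
#' @param rec An `emg_recording`.
#' @param window_ms Window duration in milliseconds.
#' @param overlap_fraction Fraction of window shared by consecutive windows.
#' @return An `emg_segment_set`: list with `windows`
#'   (`n_windows x n_channels x window_samples` array), `labels` (factor),
#'   `window_ms`, `overlap_fraction`, `fs` and `provenance` (subject,
#'   repetition per window).
#' @export
segment_recording <- function(rec, window_ms = 250, overlap_fraction = 0.5) {
  stopifnot(inherits(rec, "emg_recording"))
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop_emg("overlap_fraction must be in [0, 1)", "emg_parameter_error")
  }
  W <- round(window_ms * rec$fs / 1000)
  step <- W * (1 - overlap_fraction)  # may be fractional; starts rounded only
  ann <- rec$annotations              # for sample indexing
  starts <- integer(0); labels <- character(0); reps <- integer(0)
  for (i in seq_len(nrow(ann))) {
    T_len <- ann$offset[i] - ann$onset[i]
    if (T_len < W) {
      warning(sprintf("interval %d (%s rep %d) shorter than one window; skipped",
                      i, ann$movement[i], ann$repetition[i]))
      next
    }
    k <- floor((T_len - W) / step) + 1
    s <- round(ann$onset[i] + step * (seq_len(k) - 1))
    starts <- c(starts, as.integer(s))
    labels <- c(labels, rep(ann$movement[i], k))
    reps <- c(reps, rep(ann$repetition[i], k))
  }
  n_ch <- nrow(rec$signal)
  windows <- array(0, dim = c(length(starts), n_ch, W))
  for (j in seq_along(starts)) {
    windows[j, , ] <- rec$signal[, (starts[j] + 1):(starts[j] + W), drop = FALSE]
  }
  structure(list(windows = windows, labels = factor(labels),
                 window_ms = window_ms, overlap_fraction = overlap_fraction,
                 fs = rec$fs,
                 provenance = data.frame(subject = rep(rec$subject_id,
                                                       length(starts)),
                                         repetition = reps,
                                         start = starts,
                                         stringsAsFactors = FALSE)),
            class = "emg_segment_set")
}

#' @export
print.emg_segment_set <- function(x, ...) {
  cat(sprintf("emg_segment_set: %d windows (%g ms, %.0f%% overlap) x %d channels @ %g Hz\n",
              dim(x$windows)[1], x$window_ms, 100 * x$overlap_fraction,
              dim(x$windows)[2], x$fs))
  if (dim(x$windows)[1] > 0) print(table(x$labels))
  invisible(x)
}
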