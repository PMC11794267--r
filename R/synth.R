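#' Configuration for the synthetic sEMG generator
#'
#' Describes the acquisition protocol the generator emulates: a fixed number of
#' movement classes, each repeated `n_reps` times, every repetition lasting
#' `rep_duration` seconds followed by `rest_duration` seconds of rest, recorded
#' on `n_channels` electrodes at `fs` Hz.  Muscle activity is modelled as a
#' unit-variance stochastic carrier, band-limited to `carrier_band` Hz,
#' amplitude-modulated per movement and channel by the `gain` matrix under a
#' trapezoidal onset/offset envelope.  Rest activity is white noise band-limited
#' the same way with standard deviation `baseline_sd`; an optional 50 Hz
#' powerline component of amplitude `powerline_amp` can be superimposed.
#'
#' Units are arbitrary (gains multiply a unit-variance carrier); every
#' downstream threshold is defined relative to window statistics, never in
#' volts.
#'
#' @param n_channels Number of electrode channels.
#' @param fs Sampling rate in Hz.
#' @param movements Character vector of movement class labels.
#' @param n_reps Repetitions per movement.
#' @param rep_duration,rest_duration Seconds of movement and of rest per
#'   repetition block.
#' @param gain `n_movements x n_channels` matrix of activation amplitudes
#'   (dimensionless multiples of the unit-variance carrier).  The default
#'   assigns each movement two dominant channels (gain 3) cyclically and a
#'   deterministic 0.5--1 background on the rest, so classes are amplitude-coded
#'   and separable.
#' @param baseline_sd Standard deviation of the band-limited rest noise.
#' @param powerline_amp Amplitude of the 50 Hz interference (0 disables it).
#' @param carrier_band Length-2 vector, carrier pass band in Hz.
#' @param envelope_ramp Seconds of linear onset/offset ramp within each
#'   repetition.
#' @param seed Integer seed; identical seeds give bit-identical recordings.
#' @return An object of class `emg_synth_config`.
#' @export
synth_config <- function(n_channels = 12, fs = 2000,
                         movements = c("AF", "FF", "WE", "WRD", "WUD", "WEC"),
                         n_reps = 6, rep_duration = 5, rest_duration = 3,
                         gain = NULL, baseline_sd = 0.2, powerline_amp = 0,
                         carrier_band = c(20, 450), envelope_ramp = 0.5,
                         seed = 1L) {
  if (rep_duration <= 0 || rest_duration <= 0) {
    stop_emg("rep_duration and rest_duration must be > 0",
             "emg_configuration_error")
  }
  if (!is_count(n_reps)) {
    stop_emg("n_reps must be a positive integer", "emg_configuration_error")
  }
  if (length(carrier_band) != 2 || carrier_band[2] >= fs / 2 ||
      carrier_band[1] <= 0 || carrier_band[1] >= carrier_band[2]) {
    stop_emg("carrier_band must satisfy 0 < low < high < fs/2",
             "emg_configuration_error")
  }
  n_mov <- length(movements)
  if (is.null(gain)) gain <- default_gain(n_mov, n_channels)
  gain <- as.matrix(gain)
  if (!all(dim(gain) == c(n_mov, n_channels)) || any(gain < 0) ||
      any(!is.finite(gain))) {
    stop_emg(sprintf("gain must be a non-negative %d x %d matrix",
                     n_mov, n_channels), "emg_configuration_error")
  }
  structure(list(n_channels = n_channels, fs = fs, movements = movements,
                 n_reps = n_reps, rep_duration = rep_duration,
                 rest_duration = rest_duration, gain = gain,
                 baseline_sd = baseline_sd, powerline_amp = powerline_amp,
                 carrier_band = carrier_band, envelope_ramp = envelope_ramp,
                 seed = as.integer(seed)),
            class = "emg_synth_config")
}

# Each movement gets two dominant channels (gain 3), assigned cyclically; the
# remaining channels carry a deterministic 0.5-1 background whose pattern is
# unique per movement (coprime strides), mimicking dominant + co-activated
# muscles while keeping every class's amplitude profile distinct even when
# dominant pairs collide on small channel counts.
default_gain <- function(n_mov, n_channels) {
  g <- matrix(0, n_mov, n_channels)
  bg <- c(0.5, 0.625, 0.75, 0.875, 1)
  for (m in seq_len(n_mov)) {
    for (c in seq_len(n_channels)) {
      g[m, c] <- bg[((3 * m + 7 * c) %% 5) + 1]
    }
    dom <- ((2 * (m - 1) + c(0, 1)) %% n_channels) + 1
    g[m, dom] <- 3
  }
  g
}

#' @export
print.emg_synth_config <- function(x, ...) {
  cat(sprintf(
    "emg_synth_config: %d channels @ %g Hz, %d movements x %d reps (%gs + %gs rest)\n",
    x$n_channels, x$fs, length(x$movements), x$n_reps, x$rep_duration,
    x$rest_duration))
  cat(sprintf("  carrier %g-%g Hz, baseline_sd %g, powerline %g, seed %d\n",
              x$carrier_band[1], x$carrier_band[2], x$baseline_sd,
              x$powerline_amp, x$seed))
  invisible(x)
}

# Unit-variance carrier: white Gaussian noise bandpassed to the carrier band.
bandlimited_noise <- function(n, fs, band) {
  coefs <- butter_design(4, band / (fs / 2), "pass")
  x <- filtfilt1(coefs$b, coefs$a, rnorm(n))
  x / sd(x)
}

trapezoid_envelope <- function(n, fs, ramp) {
  t <- (seq_len(n) - 1) / fs
  dur <- n / fs
  pmin(1, pmin(t / ramp, pmax(0, (dur - t) / ramp)))
}

#' Generate a synthetic multi-channel sEMG recording
#'
#' Per channel, the signal is the sum of (i) band-limited baseline noise with
#' standard deviation `baseline_sd`, (ii) during each repetition of movement
#' `m`, `gain[m, c]` times a trapezoidal envelope times an independent
#' unit-variance band-limited carrier, and (iii) an optional 50 Hz sinusoid.
#' The session layout is all repetitions of the first movement, then the
#' second, and so on, each repetition followed by a rest block.  Movement
#' intervals are annotated with 0-based half-open sample coordinates.
#'
#' @param config An [synth_config()] object.
#' @param subject_id Identifier stored in the recording.
#' @return An object of class `emg_recording` with fields `signal`
#'   (`n_channels x n_samples`), `fs`, `annotations` (data frame with columns
#'   `onset`, `offset`, `movement`, `repetition`) and `subject_id`.
#' @export
generate_recording <- function(config, subject_id = "S1") {
  stopifnot(inherits(config, "emg_synth_config"))
  fs <- config$fs
  n_mov <- length(config$movements)
  rep_n <- round(config$rep_duration * fs)
  rest_n <- round(config$rest_duration * fs)
  block_n <- rep_n + rest_n
  n_samples <- n_mov * config$n_reps * block_n

  # amplitude profile shared by all channels up to the per-channel gain
  env <- trapezoid_envelope(rep_n, fs, config$envelope_ramp)
  onset <- integer(0); offset <- integer(0)
  movement <- character(0); repetition <- integer(0)
  amp <- matrix(0, config$n_channels, n_samples)
  blk <- 0L
  for (m in seq_len(n_mov)) {
    for (r in seq_len(config$n_reps)) {
      s0 <- blk * block_n  # 0-based start of the movement part
      idx <- (s0 + 1):(s0 + rep_n)
      for (c in seq_len(config$n_channels)) {
        amp[c, idx] <- config$gain[m, c] * env
      }
      onset <- c(onset, s0); offset <- c(offset, s0 + rep_n)
      movement <- c(movement, config$movements[m])
      repetition <- c(repetition, r)
      blk <- blk + 1L
    }
  }

  signal <- with_seed(config$seed, {
    t <- (seq_len(n_samples) - 1) / fs
    pl <- if (config$powerline_amp > 0) {
      config$powerline_amp * sin(2 * pi * 50 * t)
    } else 0
    sig <- matrix(0, config$n_channels, n_samples)
    for (c in seq_len(config$n_channels)) {
      baseline <- config$baseline_sd *
        bandlimited_noise(n_samples, fs, config$carrier_band)
      carrier <- bandlimited_noise(n_samples, fs, config$carrier_band)
      sig[c, ] <- baseline + amp[c, ] * carrier + pl
    }
    sig
  })
  rownames(signal) <- sprintf("ch%d", seq_len(config$n_channels))

  new_recording(signal, fs,
                data.frame(onset = onset, offset = offset,
                           movement = movement, repetition = repetition,
                           stringsAsFactors = FALSE),
                subject_id)
}

new_recording <- function(signal, fs, annotations, subject_id) {
  validate_annotations(annotations, ncol(signal))
  structure(list(signal = signal, fs = fs, annotations = annotations,
                 subject_id = subject_id),
            class = "emg_recording")
}

validate_annotations <- function(ann, n_samples) {
  if (nrow(ann) == 0) return(invisible(TRUE))
  if (any(ann$onset < 0) || any(ann$offset > n_samples) ||
      any(ann$offset <= ann$onset)) {
    stop_emg("annotations must be non-empty intervals within [0, n_samples)",
             "emg_format_error")
  }
  if (is.unsorted(ann$onset, strictly = TRUE) ||
      any(ann$onset[-1] < ann$offset[-nrow(ann)])) {
    stop_emg("annotations must be sorted and non-overlapping",
             "emg_format_error")
  }
  invisible(TRUE)
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("emg_recording '%s': %d channels x %d samples @ %g Hz, %d annotated movements\n",
              x$subject_id, nrow(x$signal), ncol(x$signal), x$fs,
              nrow(x$annotations)))
  invisible(x)
}
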