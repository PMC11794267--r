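# The 41-entry feature catalog: 35 time-domain and 6 frequency-domain
# statistics per window and channel.  The literature names these features but
# rarely prints equations; the conventions pinned here are the standard sEMG
# ones and are documented in the methods vignette.  All thresholds default to
# window-relative values because signal units are arbitrary.

#' Feature-extraction parameters
#'
#' @param eps_zc Dead-band amplitude for zero crossings: a crossing counts only
#'   if the two samples differ by at least this much (absolute units).
#' @param eps_ssc Slope-sign-change threshold on the product of successive
#'   slopes (absolute units; with 0 the product must be strictly positive, so
#'   constant stretches never count).
#' @param theta_wamp Wilson-amplitude threshold as a fraction of the window
#'   standard deviation; successive-difference magnitudes strictly above it
#'   count.
#' @param v_order Exponent of the V-order statistic (v = 2 would reproduce
#'   RMS; the catalog uses 3 so the two features differ).
#' @param apen_m,apen_r Approximate-entropy embedding dimension and tolerance
#'   (fraction of window SD).
#' @param card_tau Cardinality quantization step as a fraction of window SD.
#' @param fr_split Boundary in Hz between the low and high band of the
#'   frequency ratio.
#' @param log_eps Floor used inside logarithms and divisions so every feature
#'   is finite on degenerate windows.
#' @return A list of class `emg_feature_params`.
#' @export
feature_params <- function(eps_zc = 0, eps_ssc = 0, theta_wamp = 0.1,
                           v_order = 3, apen_m = 2, apen_r = 0.2,
                           card_tau = 0.01, fr_split = 250, log_eps = 1e-12) {
  if (any(c(eps_zc, eps_ssc, theta_wamp, apen_r, card_tau) < 0)) {
    stop_emg("thresholds must be >= 0", "emg_parameter_error")
  }
  if (fr_split <= 20 || fr_split >= 500) {
    stop_emg("fr_split must lie in (20, 500) Hz", "emg_parameter_error")
  }
  structure(list(eps_zc = eps_zc, eps_ssc = eps_ssc, theta_wamp = theta_wamp,
                 v_order = v_order, apen_m = apen_m, apen_r = apen_r,
                 card_tau = card_tau, fr_split = fr_split, log_eps = log_eps),
            class = "emg_feature_params")
}

# Everything a feature needs, computed once per (window, channel).
window_context <- function(x, fs, params) {
  n <- length(x)
  dx <- diff(x)
  mu <- mean(x)
  ctx <- list(x = x, n = n, dx = dx, absx = abs(x), mu = mu,
              xc = x - mu, sdev = stats::sd(x), fs = fs, p = params)
  # one-sided periodogram restricted to the 20-500 Hz analysis band
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  keep <- f >= 20 & f <= min(500, fs / 2)
  ctx$freq <- f[keep]
  ctx$psd <- (2 / (fs * n)) * Mod(X[keep])^2
  ctx
}

# Catalog order follows the field's feature tables; MAV is appended as entry 41
# so the retained-16 preset is constructible.
feature_funs <- list(
  IEMG  = function(c) sum(c$absx),
  RMS   = function(c) sqrt(sum(c$x^2) / c$n),
  VAR   = function(c) sum(c$xc^2) / (c$n - 1),
  WL    = function(c) sum(abs(c$dx)),
  ZC    = function(c) sum(c$x[-c$n] * c$x[-1] < 0 & abs(c$dx) >= c$p$eps_zc),
  SSC   = function(c) {
    pr <- c$dx[-length(c$dx)] * (-c$dx[-1])
    if (c$p$eps_ssc == 0) sum(pr > 0) else sum(pr >= c$p$eps_ssc)
  },
  MAD   = function(c) mean(abs(c$xc)),
  SSI   = function(c) sum(c$x^2),
  AE    = function(c) sum(c$x^2) / c$n,
  SKEW  = function(c) {
    m2 <- mean(c$xc^2)
    if (m2 < c$p$log_eps) 0 else mean(c$xc^3) / m2^1.5
  },
  MMAV1 = function(c) {
    i <- seq_len(c$n)
    w <- ifelse(i >= 0.25 * c$n & i <= 0.75 * c$n, 1, 0.5)
    sum(w * c$absx) / c$n
  },
  MMAV2 = function(c) {
    i <- seq_len(c$n)
    w <- ifelse(i < 0.25 * c$n, 4 * i / c$n,
                ifelse(i > 0.75 * c$n, 4 * (c$n - i) / c$n, 1))
    sum(w * c$absx) / c$n
  },
  TM3   = function(c) abs(mean(c$x^3)),
  TM4   = function(c) mean(c$x^4),
  TM5   = function(c) abs(mean(c$x^5)),
  STD   = function(c) sqrt(sum(c$xc^2) / (c$n - 1)),
  VO    = function(c) mean(c$absx^c$p$v_order)^(1 / c$p$v_order),
  LD    = function(c) exp(mean(log(c$absx + c$p$log_eps))),
  DAMV  = function(c) sum(abs(c$dx)) / (c$n - 1),
  DASDV = function(c) sqrt(sum(c$dx^2) / (c$n - 1)),
  MFL   = function(c) log10(max(sqrt(sum(c$dx^2)), c$p$log_eps)),
  LDAMV = function(c) log(max(sum(abs(c$dx)) / (c$n - 1), c$p$log_eps)),
  LCOV  = function(c) {
    s <- sqrt(sum(c$xc^2) / (c$n - 1))
    log(max(s, c$p$log_eps) / max(abs(c$mu), c$p$log_eps))
  },
  WAMP  = function(c) sum(abs(c$dx) > c$p$theta_wamp * c$sdev),
  AAC   = function(c) sum(abs(c$dx)) / (c$n - 1),
  CV    = function(c) {
    sqrt(sum(c$xc^2) / (c$n - 1)) / max(abs(c$mu), c$p$log_eps)
  },
  HMOB  = function(c) {
    v <- stats::var(c$x)
    if (v < c$p$log_eps) 0 else sqrt(stats::var(c$dx) / v)
  },
  ASS   = function(c) abs(sum(sqrt(c$absx))),
  APEN  = function(c) apen_cpp(c$x, c$p$apen_m, c$p$apen_r * c$sdev),
  CARD  = function(c) {
    step <- max(c$p$card_tau * c$sdev, c$p$log_eps)
    length(unique(round(c$x / step)))
  },
  IQ    = function(c) {
    q <- stats::quantile(c$x, c(0.25, 0.75), names = FALSE)
    q[2] - q[1]
  },
  IAV   = function(c) sum(c$absx),
  KURT  = function(c) {
    m2 <- mean(c$xc^2)
    if (m2 < c$p$log_eps) 0 else mean(c$xc^4) / m2^2 - 3
  },
  ME    = function(c) max(c$x^2),
  PF    = function(c) c$freq[which.max(c$psd)],
  MP    = function(c) mean(c$psd),
  MNF   = function(c) sum(c$freq * c$psd) / max(sum(c$psd), c$p$log_eps),
  FR    = function(c) {
    lo <- sum(c$psd[c$freq <= c$p$fr_split])
    hi <- sum(c$psd[c$freq > c$p$fr_split])
    lo / max(hi, c$p$log_eps)
  },
  TP    = function(c) sum(c$psd),
  MMF   = function(c) {
    a <- sqrt(c$psd)
    sum(c$freq * a) / max(sum(a), c$p$log_eps)
  },
  MAV   = function(c) mean(c$absx)
)

#' The feature catalog
#'
#' @return Character vector of the 41 feature names in catalog order (the
#'   35 time-domain entries first, then the 6 spectral entries, then `MAV`).
#' @export
feature_catalog <- function() names(feature_funs)

#' The 16 features retained after single-feature ranking on real recordings
#'
#' Named preset so downstream stages (reduction comparison, exhaustive subset
#' search) can run without re-ranking.
#' @return Character vector of 16 catalog names.
#' @export
paper16_features <- function() {
  c("MMAV1", "IQ", "MAD", "IAV", "IEMG", "VO", "MAV", "STD",
    "DAMV", "WL", "DASDV", "ASS", "MFL", "LDAMV", "RMS", "LD")
}

#' Compute a single catalog feature on one window
#'
#' @param name Catalog key (see [feature_catalog()]).
#' @param window Numeric sample vector, length >= 3.
#' @param fs Sampling rate in Hz (needed by the spectral features).
#' @param params [feature_params()].
#' @return A finite scalar.
#' @export
compute_feature <- function(name, window, fs = 2000,
                            params = feature_params()) {
  if (length(window) < 3) {
    stop_emg("window must have at least 3 samples", "emg_input_error")
  }
  fun <- feature_funs[[name]]
  if (is.null(fun)) {
    stop_emg(sprintf("unknown feature '%s'", name), "emg_catalog_error")
  }
  fun(window_context(as.numeric(window), fs, params))
}

new_feature_matrix <- function(values, labels, channels, features) {
  meta <- data.frame(
    channel = rep(channels, each = length(features)),
    feature = rep(features, times = length(channels)),
    stringsAsFactors = FALSE)
  structure(list(values = values, labels = labels, column_meta = meta,
                 feature_names = features, channels = channels),
            class = "emg_feature_matrix")
}

#' Extract a feature matrix from a segment set
#'
#' One row per window; columns are channel-major, catalog order within each
#' channel, named `ch{c}_{FEAT}`.  Class labels are carried through.
#'
#' @param segs An `emg_segment_set`.
#' @param names Catalog subset to extract (default: full catalog).
#' @param params [feature_params()].
#' @return An `emg_feature_matrix` with fields `values`, `labels`,
#'   `column_meta`, `feature_names`, `channels`.
#' @export
extract_features <- function(segs, names = feature_catalog(),
                             params = feature_params()) {
  stopifnot(inherits(segs, "emg_segment_set"))
  n_win <- dim(segs$windows)[1]
  n_ch <- dim(segs$windows)[2]
  if (n_win == 0) stop_emg("empty segment set", "emg_input_error")
  unknown <- setdiff(names, feature_catalog())
  if (length(unknown)) {
    stop_emg(sprintf("unknown feature(s): %s", paste(unknown, collapse = ", ")),
             "emg_catalog_error")
  }
  values <- matrix(0, n_win, n_ch * length(names))
  colnames(values) <- as.vector(vapply(seq_len(n_ch), function(c) {
    sprintf("ch%d_%s", c, names)
  }, character(length(names))))
  funs <- feature_funs[names]
  for (c in seq_len(n_ch)) {
    off <- (c - 1) * length(names)
    for (w in seq_len(n_win)) {
      ctx <- window_context(segs$windows[w, c, ], segs$fs, params)
      values[w, off + seq_along(names)] <-
        vapply(funs, function(f) f(ctx), numeric(1))
    }
  }
  if (any(!is.finite(values))) {
    stop_emg("non-finite feature value produced", "emg_input_error")
  }
  out <- new_feature_matrix(values, segs$labels, seq_len(n_ch), names)
  attr(out, "provenance") <- segs$provenance
  out
}

#' Stack feature matrices from several recordings row-wise
#'
#' All inputs must share the same channels and feature set; provenance (which
#' subject each window came from) is concatenated and kept.
#'
#' @param ... `emg_feature_matrix` objects.
#' @return An `emg_feature_matrix`.
#' @export
combine_feature_matrices <- function(...) {
  fms <- list(...)
  if (length(fms) == 1 && is.list(fms[[1]]) &&
      !inherits(fms[[1]], "emg_feature_matrix")) {
    fms <- fms[[1]]
  }
  stopifnot(length(fms) >= 1,
            all(vapply(fms, inherits, TRUE, "emg_feature_matrix")))
  ref <- fms[[1]]
  for (fm in fms[-1]) {
    if (!identical(fm$feature_names, ref$feature_names) ||
        !identical(fm$channels, ref$channels)) {
      stop_emg("feature matrices are not column-compatible",
               "emg_input_error")
    }
  }
  out <- new_feature_matrix(
    do.call(rbind, lapply(fms, `[[`, "values")),
    factor(unlist(lapply(fms, function(f) as.character(f$labels)))),
    ref$channels, ref$feature_names)
  provs <- lapply(fms, attr, "provenance")
  if (!any(vapply(provs, is.null, TRUE))) {
    attr(out, "provenance") <- do.call(rbind, provs)
  }
  out
}

#' @export
print.emg_feature_matrix <- function(x, ...) {
  cat(sprintf("emg_feature_matrix: %d windows x %d columns (%d channels x %d features)\n",
              nrow(x$values), ncol(x$values), length(x$channels),
              length(x$feature_names)))
  invisible(x)
}

#' Restrict a feature matrix to a subset of features (all channels kept)
#'
#' @param fm An `emg_feature_matrix`.
#' @param features Character vector of catalog names to keep.
#' @return An `emg_feature_matrix` with `n_channels * length(features)` columns.
#' @export
select_features <- function(fm, features) {
  stopifnot(inherits(fm, "emg_feature_matrix"))
  missing <- setdiff(features, fm$feature_names)
  if (length(missing)) {
    stop_emg(sprintf("features not in matrix: %s",
                     paste(missing, collapse = ", ")), "emg_catalog_error")
  }
  keep <- fm$column_meta$feature %in% features
  # preserve channel-major order with the requested feature order
  ord <- order(fm$column_meta$channel[keep],
               match(fm$column_meta$feature[keep], features))
  idx <- which(keep)[ord]
  new_feature_matrix(fm$values[, idx, drop = FALSE], fm$labels,
                     fm$channels, features)
}

#' Column z-scoring fitted on training rows only
#'
#' `zscore_fit()` computes per-column means and SDs on `rows` (the training
#' fold); `zscore_apply()` standardises any compatible matrix with those
#' statistics, so test folds never leak into the scaler.  Constant training
#' columns are scaled to zero with a warning.
#'
#' @param fm An `emg_feature_matrix` or plain numeric matrix.
#' @param rows Training row indices (default: all rows).
#' @param sd_floor Minimum SD used in the denominator.
#' @return `zscore_fit()`: an `emg_scaler`; `zscore_apply()`: same type as its
#'   input.
#' @export
zscore_fit <- function(fm, rows = NULL, sd_floor = 1e-12) {
  X <- if (inherits(fm, "emg_feature_matrix")) fm$values else as.matrix(fm)
  rows <- rows %||% seq_len(nrow(X))
  if (length(rows) == 0) stop_emg("training rows must be non-empty",
                                  "emg_input_error")
  Xt <- X[rows, , drop = FALSE]
  mu <- colMeans(Xt)
  sdv <- apply(Xt, 2, stats::sd)
  if (any(sdv < sd_floor)) {
    warning(sprintf("%d constant column(s) scaled to zero",
                    sum(sdv < sd_floor)))
  }
  structure(list(mean = mu, sd = pmax(sdv, sd_floor),
                 constant = sdv < sd_floor),
            class = "emg_scaler")
}

#' @rdname zscore_fit
#' @param scaler An `emg_scaler` from `zscore_fit()`.
#' @export
zscore_apply <- function(fm, scaler) {
  stopifnot(inherits(scaler, "emg_scaler"))
  is_fm <- inherits(fm, "emg_feature_matrix")
  X <- if (is_fm) fm$values else as.matrix(fm)
  Xs <- sweep(sweep(X, 2, scaler$mean, "-"), 2, scaler$sd, "/")
  Xs[, scaler$constant] <- 0
  if (is_fm) {
    fm$values <- Xs
    fm
  } else {
    Xs
  }
}
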