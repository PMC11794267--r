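# Independent, deliberately naive loop-based implementations of every catalog
# feature.  These share no code with the package (explicit accumulation loops,
# direct DFT) and exist solely to cross-check the vectorized catalog.

naive_mean <- function(x) {
  s <- 0
  for (v in x) s <- s + v
  s / length(x)
}

naive_sample_var <- function(x) {
  m <- naive_mean(x)
  s <- 0
  for (v in x) s <- s + (v - m)^2
  s / (length(x) - 1)
}

naive_central_moment <- function(x, k) {
  m <- naive_mean(x)
  s <- 0
  for (v in x) s <- s + (v - m)^k
  s / length(x)
}

# type-7 quantile by hand
naive_quantile7 <- function(x, p) {
  xs <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  xs[lo] + (h - lo) * (xs[min(lo + 1, length(x))] - xs[lo])
}

naive_periodogram <- function(x, fs) {
  n <- length(x)
  ks <- seq_len(n)
  re <- numeric(n); im <- numeric(n)
  for (k in ks) {
    for (j in seq_len(n)) {
      ang <- -2 * pi * (k - 1) * (j - 1) / n
      re[k] <- re[k] + x[j] * cos(ang)
      im[k] <- im[k] + x[j] * sin(ang)
    }
  }
  f <- (ks - 1) * fs / n
  keep <- f >= 20 & f <= min(500, fs / 2)
  list(f = f[keep], P = (2 / (fs * n)) * (re[keep]^2 + im[keep]^2))
}

naive_apen <- function(x, m, r) {
  n <- length(x)
  phi <- numeric(2)
  for (s in 0:1) {
    mm <- m + s
    nv <- n - mm + 1
    acc <- 0
    for (i in seq_len(nv)) {
      cnt <- 0
      for (j in seq_len(nv)) {
        d <- 0
        for (k in 0:(mm - 1)) {
          dd <- abs(x[i + k] - x[j + k])
          if (dd > d) d <- dd
        }
        if (d <= r) cnt <- cnt + 1
      }
      acc <- acc + log(cnt / nv)
    }
    phi[s + 1] <- acc / nv
  }
  phi[1] - phi[2]
}

# One naive value per catalog feature; conventions restated from scratch.
naive_feature <- function(name, x, fs, p = feature_params()) {
  n <- length(x)
  dx <- numeric(n - 1)
  for (i in seq_len(n - 1)) dx[i] <- x[i + 1] - x[i]
  mu <- naive_mean(x)
  sdev <- sqrt(naive_sample_var(x))
  absx <- abs(x)
  switch(name,
    IEMG = , IAV = { s <- 0; for (v in absx) s <- s + v; s },
    MAV = naive_mean(absx),
    RMS = { s <- 0; for (v in x) s <- s + v^2; sqrt(s / n) },
    VAR = naive_sample_var(x),
    STD = sqrt(naive_sample_var(x)),
    WL = { s <- 0; for (v in dx) s <- s + abs(v); s },
    ZC = {
      cnt <- 0
      for (i in seq_len(n - 1)) {
        if (x[i] * x[i + 1] < 0 && abs(x[i] - x[i + 1]) >= p$eps_zc) {
          cnt <- cnt + 1
        }
      }
      cnt
    },
    SSC = {
      cnt <- 0
      for (i in 2:(n - 1)) {
        pr <- (x[i] - x[i - 1]) * (x[i] - x[i + 1])
        ok <- if (p$eps_ssc == 0) pr > 0 else pr >= p$eps_ssc
        if (ok) cnt <- cnt + 1
      }
      cnt
    },
    MAD = { s <- 0; for (v in x) s <- s + abs(v - mu); s / n },
    SSI = { s <- 0; for (v in x) s <- s + v^2; s },
    AE = { s <- 0; for (v in x) s <- s + v^2; s / n },
    ME = { mx <- -Inf; for (v in x) mx <- max(mx, v^2); mx },
    SKEW = {
      m2 <- naive_central_moment(x, 2)
      if (m2 < p$log_eps) 0 else naive_central_moment(x, 3) / m2^1.5
    },
    KURT = {
      m2 <- naive_central_moment(x, 2)
      if (m2 < p$log_eps) 0 else naive_central_moment(x, 4) / m2^2 - 3
    },
    MMAV1 = {
      s <- 0
      for (i in seq_len(n)) {
        w <- if (i >= 0.25 * n && i <= 0.75 * n) 1 else 0.5
        s <- s + w * absx[i]
      }
      s / n
    },
    MMAV2 = {
      s <- 0
      for (i in seq_len(n)) {
        w <- if (i < 0.25 * n) 4 * i / n
             else if (i > 0.75 * n) 4 * (n - i) / n
             else 1
        s <- s + w * absx[i]
      }
      s / n
    },
    TM3 = abs(naive_mean(x^3)),
    TM4 = naive_mean(x^4),
    TM5 = abs(naive_mean(x^5)),
    VO = naive_mean(absx^p$v_order)^(1 / p$v_order),
    LD = { s <- 0; for (v in absx) s <- s + log(v + p$log_eps); exp(s / n) },
    DAMV = , AAC = { s <- 0; for (v in dx) s <- s + abs(v); s / (n - 1) },
    DASDV = { s <- 0; for (v in dx) s <- s + v^2; sqrt(s / (n - 1)) },
    MFL = { s <- 0; for (v in dx) s <- s + v^2; log10(max(sqrt(s), p$log_eps)) },
    LDAMV = {
      s <- 0; for (v in dx) s <- s + abs(v)
      log(max(s / (n - 1), p$log_eps))
    },
    LCOV = log(max(sdev, p$log_eps) / max(abs(mu), p$log_eps)),
    WAMP = { cnt <- 0; for (v in dx) if (abs(v) > p$theta_wamp * sdev) cnt <- cnt + 1; cnt },
    CV = sdev / max(abs(mu), p$log_eps),
    HMOB = {
      vx <- naive_sample_var(x)
      if (vx < p$log_eps) 0 else sqrt(naive_sample_var(dx) / vx)
    },
    ASS = { s <- 0; for (v in absx) s <- s + sqrt(v); abs(s) },
    APEN = naive_apen(x, p$apen_m, p$apen_r * sdev),
    CARD = {
      step <- max(p$card_tau * sdev, p$log_eps)
      r <- round(x / step)
      cnt <- 1
      rs <- sort(r)
      for (i in 2:length(rs)) if (rs[i] != rs[i - 1]) cnt <- cnt + 1
      cnt
    },
    IQ = naive_quantile7(x, 0.75) - naive_quantile7(x, 0.25),
    PF = { pg <- naive_periodogram(x, fs); pg$f[which.max(pg$P)] },
    MP = { pg <- naive_periodogram(x, fs); naive_mean(pg$P) },
    MNF = {
      pg <- naive_periodogram(x, fs)
      sum(pg$f * pg$P) / max(sum(pg$P), p$log_eps)
    },
    FR = {
      pg <- naive_periodogram(x, fs)
      lo <- 0; hi <- 0
      for (i in seq_along(pg$f)) {
        if (pg$f[i] <= p$fr_split) lo <- lo + pg$P[i] else hi <- hi + pg$P[i]
      }
      lo / max(hi, p$log_eps)
    },
    TP = { pg <- naive_periodogram(x, fs); sum(pg$P) },
    MMF = {
      pg <- naive_periodogram(x, fs)
      a <- sqrt(pg$P)
      sum(pg$f * a) / max(sum(a), p$log_eps)
    },
    stop("no oracle for ", name)
  )
}

# Brute-force window-count oracle: enumerate real-valued start positions.
naive_window_count <- function(T_len, W, overlap) {
  step <- W * (1 - overlap)
  cnt <- 0
  s <- 0
  while (s + W <= T_len + 1e-9) {
    cnt <- cnt + 1
    s <- s + step
  }
  cnt
}

# From-scratch one-way ANOVA oracle (sums of squares written out).
naive_anova <- function(groups) {
  allx <- unlist(groups)
  grand <- naive_mean(allx)
  ssb <- 0; ssw <- 0
  for (g in groups) {
    m <- naive_mean(g)
    ssb <- ssb + length(g) * (m - grand)^2
    for (v in g) ssw <- ssw + (v - m)^2
  }
  dfb <- length(groups) - 1
  dfw <- length(allx) - length(groups)
  Fv <- (ssb / dfb) / (ssw / dfw)
  list(F = Fv, dfb = dfb, dfw = dfw,
       p = stats::pf(Fv, dfb, dfw, lower.tail = FALSE))
}
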