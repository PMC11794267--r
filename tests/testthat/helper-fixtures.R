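# Fixtures shared across test files, built once per run and cached.
# Everything is generated in code from fixed seeds; no data files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# Small 6-channel session: 6 movements x 2 reps, enough windows for 5-fold CV.
small_recording <- function() {
  fixture("small_recording", function() {
    generate_recording(synth_config(n_channels = 6, n_reps = 2, seed = 101),
                       "S1")
  })
}

small_segments <- function() {
  fixture("small_segments", function() segment_recording(small_recording()))
}

# paper16 feature matrix of the small session (192 windows would be 6ch x 16).
small_fm16 <- function() {
  fixture("small_fm16", function() {
    extract_features(small_segments(), paper16_features())
  })
}

# Default-shape 12-channel session and its paper16 matrix.
default_fm16 <- function() {
  fixture("default_fm16", function() {
    rec <- generate_recording(synth_config(n_reps = 2, seed = 202), "S1")
    extract_features(segment_recording(rec), paper16_features())
  })
}

fast_cfg <- function(seed = 1L) ann_config(profile = "fast", seed = seed)

# Two well-separated Gaussian blobs.
make_blobs <- function(n = 200, sep = 10, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n / 2 * 2), n / 2, 2),
             matrix(rnorm(n / 2 * 2, mean = sep), n / 2, 2))
  list(X = X, y = rep(c("a", "b"), each = n / 2))
}

# Gaussian class-coded feature matrix: `informative` columns carry the class
# mean pattern, the rest are pure noise.  Returned as emg_feature_matrix with
# one channel so subset search can consume it.
make_planted_fm <- function(n_per_class = 50, n_classes = 6, n_features = 8,
                            informative = c(1, 2), sep = 2, seed = 1) {
  set.seed(seed)
  n <- n_per_class * n_classes
  y <- factor(rep(paste0("c", seq_len(n_classes)), each = n_per_class))
  X <- matrix(rnorm(n * n_features), n, n_features)
  # class means on a circle so that both planted columns are needed jointly
  ang <- 2 * pi * (seq_len(n_classes) - 1) / n_classes
  mu <- sep * cbind(cos(ang), sin(ang))
  for (ci in seq_len(n_classes)) {
    rows <- y == paste0("c", ci)
    X[rows, informative[1]] <- X[rows, informative[1]] + mu[ci, 1]
    X[rows, informative[2]] <- X[rows, informative[2]] + mu[ci, 2]
  }
  feats <- paste0("F", seq_len(n_features))
  colnames(X) <- paste0("ch1_", feats)
  fm <- emgselect:::new_feature_matrix(X, y, 1L, feats)
  fm
}
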