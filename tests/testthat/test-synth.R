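test_that("generation is bit-deterministic under a fixed seed", {
  cfg <- synth_config(n_channels = 3, n_reps = 1, seed = 7)
  r1 <- generate_recording(cfg)
  r2 <- generate_recording(cfg)
  expect_identical(r1$signal, r2$signal)
  expect_identical(r1$annotations, r2$annotations)
  r3 <- generate_recording(synth_config(n_channels = 3, n_reps = 1, seed = 8))
  expect_false(identical(r1$signal, r3$signal))
})

test_that("recording layout matches the session protocol", {
  cfg <- synth_config(n_channels = 4, n_reps = 2, rep_duration = 5,
                      rest_duration = 3, seed = 1)
  rec <- generate_recording(cfg)
  expect_equal(ncol(rec$signal), 6 * 2 * (5 + 3) * 2000)
  expect_equal(nrow(rec$annotations), 12)
  expect_equal(rec$annotations$offset - rec$annotations$onset,
               rep(5 * 2000, 12))
  # sorted, non-overlapping, half-open
  expect_true(all(diff(rec$annotations$onset) > 0))
  expect_true(all(rec$annotations$onset[-1] >=
                    rec$annotations$offset[-12]))
})

test_that("zero gain leaves movement windows statistically at rest level", {
  cfg <- synth_config(n_channels = 2, n_reps = 2,
                      gain = matrix(0, 6, 2), powerline_amp = 0,
                      baseline_sd = 1, seed = 3)
  rec <- generate_recording(cfg)
  rms <- function(x) sqrt(mean(x^2))
  ann <- rec$annotations
  mov_idx <- unlist(mapply(function(a, b) (a + 1):b, ann$onset, ann$offset,
                           SIMPLIFY = FALSE))
  rest_idx <- setdiff(seq_len(ncol(rec$signal)), mov_idx)
  ratio <- rms(rec$signal[1, mov_idx]) / rms(rec$signal[1, rest_idx])
  expect_lt(abs(ratio - 1), 0.1)
})

test_that("plateau window RMS follows variance additivity of carrier and baseline", {
  # gain 3 on unit-variance carrier over baseline_sd 1: RMS ~ sqrt(10)
  cfg <- synth_config(n_channels = 1, n_reps = 4,
                      gain = matrix(3, 6, 1), baseline_sd = 1,
                      powerline_amp = 0, seed = 5)
  rec <- generate_recording(cfg)
  ann <- rec$annotations
  fs <- rec$fs
  vals <- c()
  for (i in seq_len(nrow(ann))) {
    # plateau: skip the 0.5 s ramps at each end
    lo <- ann$onset[i] + fs
    hi <- ann$offset[i] - fs
    starts <- seq(lo, hi - 500, by = 500)
    vals <- c(vals, vapply(starts, function(s) {
      sqrt(mean(rec$signal[1, (s + 1):(s + 500)]^2))
    }, 0))
  }
  expect_gte(length(vals), 20)
  expect_lt(abs(mean(vals) - sqrt(10)) / sqrt(10), 0.1)
})

test_that("powerline interference dominates the rest-interval periodogram at 50 Hz", {
  cfg <- synth_config(n_channels = 1, n_reps = 1, baseline_sd = 0.01,
                      powerline_amp = 1, gain = matrix(0.5, 6, 1), seed = 9)
  rec <- generate_recording(cfg)
  # rest block after the first repetition
  a <- rec$annotations
  seg <- rec$signal[1, (a$offset[1] + 1):(a$onset[2])]
  n <- length(seg)
  P <- Mod(stats::fft(seg))^2
  f <- (seq_len(n) - 1) * rec$fs / n
  half <- f <= rec$fs / 2
  fpeak <- f[half][which.max(P[half])]
  expect_lt(abs(fpeak - 50), rec$fs / n + 1e-9)
})

test_that("class separability responds monotonically to gain contrast", {
  # doubling the inter-movement gain contrast must not reduce CV accuracy
  # (tolerance: 2 points), at a noise level where accuracy has headroom
  acc_at <- function(contrast, seed) {
    base <- emgselect:::default_gain(6, 6)
    gm <- mean(base)
    g <- gm + contrast * (base - gm)
    sc <- synth_config(n_channels = 6, n_reps = 2, gain = g,
                       baseline_sd = 1.5, seed = seed)
    fm <- extract_features(segment_recording(generate_recording(sc)),
                           c("RMS", "WL"))
    evaluate_cv(fm$values, fm$labels, fast_cfg(seed = seed),
                seed = seed)$mean_accuracy
  }
  for (s in 1:3) {
    lo <- acc_at(0.5, 500 + s)
    hi <- acc_at(1.0, 500 + s)
    expect_gte(hi, lo - 0.02)
  }
})

test_that("invalid configurations are refused", {
  expect_error(synth_config(gain = matrix(1, 2, 2)),
               class = "emg_configuration_error")
  expect_error(synth_config(rep_duration = 0),
               class = "emg_configuration_error")
  expect_error(synth_config(carrier_band = c(20, 1500)),
               class = "emg_configuration_error")
  expect_error(synth_config(n_reps = 0), class = "emg_configuration_error")
})

test_that("recordings round-trip through the TSV + sidecar format", {
  rec <- generate_recording(synth_config(n_channels = 2, n_reps = 1,
                                         rep_duration = 0.5,
                                         rest_duration = 0.5, seed = 2))
  path <- file.path(tempdir(), "rec_roundtrip.tsv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$annotations$onset, rec$annotations$onset)
  expect_equal(back$annotations$movement, rec$annotations$movement)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$subject_id, rec$subject_id)
  expect_lt(max(abs(back$signal - rec$signal)), 1e-9)
  unlink(c(path, paste0(path, ".json")))
})

test_that("recording IO contract failures are explicit", {
  rec <- generate_recording(synth_config(n_channels = 2, n_reps = 1,
                                         rep_duration = 0.5,
                                         rest_duration = 0.5, seed = 2))
  path <- file.path(tempdir(), "rec_bad.tsv")
  write_recording(rec, path)
  # missing sidecar
  file.remove(paste0(path, ".json"))
  expect_error(read_recording(path), class = "emg_format_error")
  # sidecar without fs
  jsonlite::write_json(list(subject_id = "x"), paste0(path, ".json"),
                       auto_unbox = TRUE)
  expect_error(read_recording(path), class = "emg_format_error")
  unlink(c(path, paste0(path, ".json")))
})

test_that("an empty annotation table round-trips as a valid file", {
  sig <- matrix(rnorm(200), 2, 100)
  rec <- emgselect:::new_recording(
    sig, 2000,
    data.frame(onset = integer(0), offset = integer(0),
               movement = character(0), repetition = integer(0)),
    "S0")
  path <- file.path(tempdir(), "rec_empty.tsv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(nrow(back$annotations), 0)
  expect_lt(max(abs(back$signal - sig)), 1e-9)
  unlink(c(path, paste0(path, ".json")))
})
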