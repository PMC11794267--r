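test_that("worked arithmetic examples hold exactly", {
  expect_equal(compute_feature("RMS", c(3, -4, 0)), sqrt(25 / 3))
  expect_equal(compute_feature("RMS", c(3, -4, 3, -4)), sqrt(12.5))
  expect_equal(compute_feature("WL", rep(2.5, 10)), 0)
  expect_equal(compute_feature("ZC", c(1, -1, 1, -1)), 3)
  expect_equal(compute_feature("MFL", c(0, 1, 0)), log10(sqrt(2)))
  expect_equal(compute_feature("DAMV", c(0, 1, 3)), 1.5)
  expect_equal(compute_feature("LDAMV", c(0, 1, 3)), log(1.5))
  expect_error(compute_feature("RMS", c(1, 2)), class = "emg_input_error")
  expect_error(compute_feature("NOPE", rnorm(10)),
               class = "emg_catalog_error")
})

test_that("peak frequency localises a pure tone to one periodogram bin", {
  fs <- 2000
  x <- sin(2 * pi * 100 * seq_len(500) / fs)
  expect_lt(abs(compute_feature("PF", x, fs) - 100), fs / 500 + 1e-9)
})

test_that("every catalog formula matches its naive loop oracle", {
  # 100 seeded random windows; short windows keep the O(n^2) DFT oracle cheap
  set.seed(515)
  params <- feature_params()
  worst <- 0
  for (i in 1:100) {
    n <- sample(c(48, 64, 100), 1)
    x <- rnorm(n, sd = runif(1, 0.5, 3)) + runif(1, -1, 1)
    for (name in feature_catalog()) {
      got <- compute_feature(name, x, fs = 2000, params = params)
      want <- naive_feature(name, x, fs = 2000, p = params)
      denom <- max(abs(want), 1e-300)
      rel <- abs(got - want) / denom
      if (abs(want) < 1e-12) rel <- abs(got - want)
      worst <- max(worst, rel)
      if (rel >= 1e-10) {
        fail(sprintf("feature %s: got %.15g want %.15g (window %d)",
                     name, got, want, i))
      }
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("duplicate feature identities hold exactly", {
  set.seed(99)
  for (i in 1:20) {
    x <- rnorm(200)
    expect_identical(compute_feature("IAV", x), compute_feature("IEMG", x))
    expect_identical(compute_feature("AAC", x), compute_feature("DAMV", x))
    expect_identical(compute_feature("STD", x),
                     sqrt(compute_feature("VAR", x)))
    expect_identical(compute_feature("AE", x),
                     compute_feature("SSI", x) / length(x))
  }
})

test_that("degenerate windows give guarded finite values", {
  const <- rep(1.3, 100)
  for (name in c("WL", "ZC", "SSC", "WAMP")) {
    expect_equal(compute_feature(name, const), 0, info = name)
  }
  expect_equal(compute_feature("APEN", const), 0)
  for (name in feature_catalog()) {
    v <- compute_feature(name, const)
    expect_true(is.finite(v), info = name)
    v0 <- compute_feature(name, rep(0, 100))
    expect_true(is.finite(v0), info = paste0(name, " @zero"))
  }
})

test_that("approximate entropy orders noise above a sinusoid", {
  n <- 300
  t <- seq_len(n) / 2000
  for (s in 1:20) {
    set.seed(s)
    noise <- rnorm(n)
    sine <- sin(2 * pi * 50 * t)
    expect_gt(compute_feature("APEN", noise), compute_feature("APEN", sine),
              label = sprintf("seed %d: ApEn(noise)", s))
  }
})

test_that("feature homogeneity degrees behave under amplitude scaling", {
  set.seed(7)
  x <- rnorm(400)
  deg1 <- c("RMS", "IEMG", "WL", "MAD", "STD", "DASDV", "IQ", "MAV", "VO")
  deg0 <- c("ZC", "SSC", "SKEW", "KURT", "HMOB", "CV", "CARD", "WAMP",
            "PF", "MNF", "FR", "MMF")
  for (name in deg1) {
    expect_equal(compute_feature(name, 10 * x),
                 10 * compute_feature(name, x), tolerance = 1e-12,
                 info = name)
  }
  for (name in deg0) {
    expect_equal(compute_feature(name, 10 * x), compute_feature(name, x),
                 tolerance = 1e-12, info = name)
  }
})

test_that("extract_features produces the documented shape and ordering", {
  segs <- small_segments()
  fm <- small_fm16()
  expect_equal(dim(fm$values),
               c(dim(segs$windows)[1], 6 * 16))
  expect_equal(colnames(fm$values)[1:3],
               c("ch1_MMAV1", "ch1_IQ", "ch1_MAD"))
  expect_equal(colnames(fm$values)[17], "ch2_MMAV1")
  expect_identical(fm$labels, segs$labels)
  expect_true(all(is.finite(fm$values)))
  # spot-check one cell against compute_feature
  expect_equal(unname(fm$values[5, "ch3_RMS"]),
               compute_feature("RMS", segs$windows[5, 3, ], segs$fs))
  expect_error(extract_features(segs, c("RMS", "BOGUS")),
               class = "emg_catalog_error")
})

test_that("feature matrices round-trip to CSV bit-stably", {
  fm <- small_fm16()
  p1 <- file.path(tempdir(), "fm1.csv")
  p2 <- file.path(tempdir(), "fm2.csv")
  write_feature_matrix(fm, p1)
  write_feature_matrix(fm, p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- read_feature_matrix(p1)
  expect_equal(back$values, fm$values, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(as.character(back$labels), as.character(fm$labels))
  expect_identical(back$feature_names, fm$feature_names)
  unlink(c(p1, p2))
})

test_that("z-scoring is fit on training rows only", {
  set.seed(31)
  X <- matrix(rnorm(200, mean = 5, sd = 2), 20, 10)
  sc <- zscore_fit(X)
  Xs <- zscore_apply(X, sc)
  expect_lt(max(abs(colMeans(Xs))), 1e-10)
  expect_lt(max(abs(apply(Xs, 2, sd) - 1)), 1e-10)

  # scaler fit on rows 1..15 applied to rows 16..20 uses training statistics
  tr <- 1:15
  sc2 <- zscore_fit(X, tr)
  expect_equal(sc2$mean, colMeans(X[tr, ]))
  hand_sd <- apply(X[tr, ], 2, sd)
  expect_equal(unname(sc2$sd), unname(hand_sd))
  Xte <- zscore_apply(X[16:20, ], sc2)
  expect_equal(Xte, sweep(sweep(X[16:20, ], 2, colMeans(X[tr, ])), 2,
                          hand_sd, "/"))
  expect_gt(max(abs(colMeans(Xte))), 1e-6)  # test means are not re-centered

  # constant column warns and maps to zero
  Xc <- cbind(X, 3)
  expect_warning(scc <- zscore_fit(Xc), "constant")
  expect_true(all(zscore_apply(Xc, scc)[, 11] == 0))
})
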