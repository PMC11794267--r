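test_that("PCA reproduces the eigendecomposition oracle", {
  set.seed(10)
  X <- matrix(rnorm(1000), 100, 10)
  emb <- pca_fit(X, 3)
  ev <- eigen(cov(X), symmetric = TRUE)$values
  got <- apply(emb$latent, 2, var)
  expect_lt(max(abs(got - ev[1:3]) / ev[1:3]), 1e-8)
  expect_true(all(diff(emb$explained_variance) <= 1e-12))
  expect_lte(sum(emb$explained_variance), 1 + 1e-12)
  # orthonormal loadings
  expect_equal(crossprod(emb$loadings), diag(3), tolerance = 1e-10)

  # degenerate covariance: all variance on axis 1
  X2 <- cbind(rnorm(50), 0)
  e2 <- pca_fit(X2, 2)
  expect_gt(abs(e2$loadings[1, 1]), 0.999999)
  expect_lt(e2$explained_variance[2], 1e-10)

  # full-rank reconstruction is the identity
  ef <- pca_fit(X, 10)
  Xhat <- sweep(ef$latent %*% t(ef$loadings), 2, colMeans(X), "+")
  expect_lt(max(abs(Xhat - X)), 1e-8)
  expect_error(pca_fit(X, 11), class = "emg_parameter_error")
})

test_that("LDA finds the separating axis and reports rank bounds", {
  set.seed(11)
  X <- matrix(rnorm(1200), 200, 6)
  y <- rep(c("a", "b"), each = 100)
  X[y == "b", 1] <- X[y == "b", 1] + 6
  emb <- lda_fit(X, y, 1)
  v <- emb$directions / sqrt(sum(emb$directions^2))
  expect_gt(abs(v[1]), 0.99)
  # cross-check the direction against the MASS implementation
  skip_if_not_installed("MASS")
  m <- MASS::lda(X, grouping = y)
  vm <- m$scaling / sqrt(sum(m$scaling^2))
  expect_gt(abs(sum(v * vm)), 0.999)
})

test_that("LDA refuses collinear inputs with a named singular-scatter error", {
  set.seed(12)
  X <- matrix(rnorm(600), 100, 6)
  colnames(X) <- paste0("f", 1:6)
  y <- rep(c("a", "b"), each = 50)
  Xd <- cbind(X, f1_copy = X[, 1])
  err <- expect_error(lda_fit(Xd, y, 1),
                      class = "emg_singular_scatter_error")
  expect_match(conditionMessage(err), "f1_copy|f1")
  expect_error(lda_fit(X, y, 2), class = "emg_parameter_error")
  # the ridge escape hatch fits anyway
  expect_s3_class(lda_fit(Xd, y, 1, ridge = 1e-6), "emg_embedding")
})

test_that("PPCA EM recovers planted factor structure", {
  set.seed(13)
  W0 <- matrix(rnorm(20), 10, 2)
  Z <- matrix(rnorm(1000), 500, 2)
  X <- Z %*% t(W0) + matrix(rnorm(5000, sd = 0.1), 500, 10)
  emb <- suppressWarnings(ppca_em(X, 2, seed = 5))
  expect_lt(abs(emb$sigma2 - 0.01) / 0.01, 0.2)
  expect_lt(max(principal_angles(emb$W, W0)), 0.05)
})

test_that("PPCA log-likelihood is monotone and approaches PCA as noise vanishes", {
  for (s in 1:10) {
    set.seed(s)
    X <- matrix(rnorm(60 * 6), 60, 6) %*% diag(c(3, 2, 1, .5, .3, .2))
    emb <- suppressWarnings(ppca_em(X, 2, seed = s, max_iter = 200))
    expect_true(all(diff(emb$loglik_trace) > -1e-9),
                info = sprintf("seed %d", s))
  }
  set.seed(14)
  W0 <- matrix(rnorm(16), 8, 2)
  Z <- matrix(rnorm(600), 300, 2)
  X <- Z %*% t(W0) + matrix(rnorm(2400, sd = 1e-4), 300, 8)
  emb <- suppressWarnings(ppca_em(X, 2, seed = 3, max_iter = 2000))
  pc <- pca_fit(X, 2)
  expect_lt(max(principal_angles(emb$W, pc$loadings)), 1e-2)
  expect_error(ppca_em(X, 8), class = "emg_parameter_error")
})

test_that("GPLVM objective descends from its PCA initialisation", {
  for (s in 1:10) {
    set.seed(s)
    X <- matrix(rnorm(60 * 5), 60, 5)
    emb <- gplvm_fit(X, 2, max_iter = 30)
    expect_true(all(diff(emb$objective_trace) <= 0),
                info = sprintf("seed %d", s))
    expect_lte(emb$objective_trace[length(emb$objective_trace)],
               emb$init_objective)
  }
})

test_that("linear-kernel GPLVM stays on the PCA subspace for factor data", {
  set.seed(15)
  W0 <- matrix(rnorm(16), 8, 2)
  Z <- matrix(rnorm(300), 150, 2)
  X <- Z %*% t(W0) + matrix(rnorm(1200, sd = 0.1), 150, 8)
  emb <- gplvm_fit(X, 2, kernel = "linear", max_iter = 100)
  pc <- pca_fit(X, 2)
  expect_lt(max(principal_angles(emb$latent_fit, pc$latent)), 0.05)
})

test_that("GPLVM beats linear PCA on a 1-D nonlinear manifold", {
  wins <- 0
  for (s in 1:10) {
    set.seed(s)
    t <- seq(0, 3 * pi, length.out = 100)
    Y <- cbind(t, sin(t), cos(t)) + matrix(rnorm(300, sd = 0.05), 100, 3)
    g <- gplvm_fit(Y, 1, kernel = "rbf", max_iter = 60)
    err_g <- mean((g$reconstruct() - Y)^2)
    pc <- pca_fit(Y, 1)
    Yp <- sweep(pc$latent %*% t(pc$loadings), 2, colMeans(Y), "+")
    err_p <- mean((Yp - Y)^2)
    if (err_g < err_p) wins <- wins + 1
  }
  expect_gte(wins, 8)
})

test_that("GPLVM guards dense kernel algebra on large row counts", {
  X <- matrix(rnorm(40), 20, 2)
  expect_error(gplvm_fit(X, 1, max_rows = 10),
               class = "emg_parameter_error")
  emb <- gplvm_fit(cbind(X, rnorm(20)), 1, max_rows = 10, subsample = 10,
                   max_iter = 10, seed = 2)
  expect_equal(nrow(emb$latent), 20)   # all rows mapped out-of-sample
  expect_equal(nrow(emb$latent_fit), 10)
})

test_that("ReliefF ranks planted features above noise in every seeded run", {
  for (s in 1:20) {
    set.seed(s)
    n <- 90
    y <- rep(c("a", "b", "c"), each = n / 3)
    X <- cbind(as.integer(factor(y)) + rnorm(n, sd = 0.1),
               matrix(rnorm(n * 5), n, 5))
    Xs <- zscore_apply(X, zscore_fit(X))
    mask <- relieff(Xs, y, k_neighbors = 5, n_select = 1)
    expect_gt(mask$weights[1], max(mask$weights[-1]),
              label = sprintf("seed %d informative weight", s))
    expect_equal(mask$selected, 1L)
  }
})

test_that("ReliefF weight symmetry and guards", {
  set.seed(16)
  n <- 60
  y <- rep(c("a", "b"), each = n / 2)
  inf <- as.integer(factor(y)) + rnorm(n, sd = 0.1)
  X <- cbind(inf, inf + rnorm(n, sd = 0.01), matrix(rnorm(n * 3), n, 3))
  Xs <- zscore_apply(X, zscore_fit(X))
  mask <- relieff(Xs, y, k_neighbors = 5, n_select = 5)
  # duplicated informative feature: weights agree within 10%
  expect_lt(abs(mask$weights[1] - mask$weights[2]) /
              max(abs(mask$weights[1:2])), 0.1)
  expect_equal(sort(relieff(Xs, y, 5, n_select = ncol(Xs))$selected),
               seq_len(ncol(Xs)))
  expect_error(relieff(Xs[1:8, ], y[1:8], k_neighbors = 10),
               class = "emg_parameter_error")
})

test_that("Lasso recovers a planted sparse predictor", {
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    n <- 200
    y <- rep(c("a", "b"), each = n / 2)
    X <- cbind(matrix(rnorm(n * 20), n, 20),
               ifelse(y == "b", 3, 0) + rnorm(n, sd = 0.3))
    mask <- lasso_select(X, y, seed = s)
    if (identical(mask$selected, 21L)) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("Lasso penalty limits behave as documented", {
  set.seed(17)
  n <- 120
  y <- rep(c("a", "b"), each = n / 2)
  X <- cbind(ifelse(y == "b", 2, 0) + rnorm(n, sd = 0.5),
             matrix(rnorm(n * 4), n, 4))
  # unpenalised limit: everything enters
  tiny <- lasso_select(X, y, lambda_grid = c(1e-4, 1e-5), seed = 1)
  expect_equal(sort(tiny$selected), 1:5)
  # fully penalised limit: explicit empty-selection warning, smallest-lambda fallback
  expect_warning(big <- lasso_select(X, y, lambda_grid = c(50, 20), seed = 1),
                 "smallest lambda")
  expect_s3_class(big, "emg_selection")
})

test_that("evaluate_reduction honours the identity route and full-rank rotation", {
  fm <- small_fm16()
  cfg <- fast_cfg(seed = 5)
  folds <- stratified_folds(fm$labels, 5, seed = 31)
  r_none <- evaluate_reduction(fm, "none", cfg = cfg, folds = folds)
  r_cv <- evaluate_cv(fm$values, fm$labels, cfg, folds = folds)
  expect_identical(r_none$report$fold_accuracies, r_cv$fold_accuracies)
  # full-rank PCA is a rotation: accuracy within one point of the identity
  r_rot <- evaluate_reduction(fm, "pca", list(d = ncol(fm$values)),
                              cfg = cfg, folds = folds)
  expect_lt(abs(r_rot$report$mean_accuracy - r_none$report$mean_accuracy),
            0.01 + 1e-9)
})

test_that("all reduction methods stay near the unreduced accuracy", {
  fm <- default_fm16()
  cfg <- fast_cfg(seed = 2)
  for (s in 1:3) {
    cmp <- compare_reductions(fm, cfg = cfg, seed = 40 + s)
    none_acc <- cmp$mean_accuracy[cmp$method == "none"]
    ok <- cmp$error == ""
    expect_true(all(abs(cmp$mean_accuracy[ok] - none_acc) <= 0.05),
                info = sprintf("seed %d: %s", s,
                               paste(sprintf("%s=%.3f", cmp$method[ok],
                                             cmp$mean_accuracy[ok]),
                                     collapse = " ")))
    # LDA fails on the duplicate-feature catalog, as on the real data
    expect_match(cmp$error[cmp$method == "lda"], "singular")
  }
})
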