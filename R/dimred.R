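# Six reduction / selection routes under one interface.  Every fitted object
# carries a `transform(X)` closure for new rows so the cross-validation
# harness can fit on training folds and map held-out folds without leakage.
#
# PCA is the eigendecomposition oracle the probabilistic models are checked
# against; PPCA is fit by expectation-maximisation (its log-likelihood trace
# must never decrease); the GPLVM minimises the negative GP marginal
# log-likelihood over latent coordinates and kernel hyperparameters by
# gradient descent with a backtracking line search, so its objective trace is
# non-increasing by construction.

#' Principal component analysis
#'
#' @param X Numeric matrix (rows = observations); centered internally.
#' @param d Latent dimension, `<= min(n_rows, n_cols)`.
#' @return An `emg_embedding` with orthonormal `loadings`, `latent` scores,
#'   `explained_variance` fractions (descending) and a `transform` closure.
#' @export
pca_fit <- function(X, d) {
  X <- as.matrix(X)
  if (!is_count(d) || d > min(dim(X))) {
    stop_emg("d must be a positive integer <= min(n_rows, n_cols)",
             "emg_parameter_error")
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0, nv = min(dim(X)))
  ev <- sv$d^2 / max(1, nrow(X) - 1)
  W <- sv$v[, seq_len(d), drop = FALSE]
  structure(list(method = "pca", d = d, loadings = W,
                 latent = Xc %*% W,
                 explained_variance = ev[seq_len(d)] / sum(ev),
                 eigenvalues = ev, center = mu,
                 transform = function(Xnew) {
                   sweep(as.matrix(Xnew), 2, mu) %*% W
                 }),
            class = "emg_embedding")
}

# Smallest number of leading components reaching `target` variance fraction.
pca_dim_for_variance <- function(X, target = 0.95) {
  ev <- pca_fit(X, 1)$eigenvalues
  max(1L, which(cumsum(ev) / sum(ev) >= target)[1])
}

#' Linear discriminant analysis (generalized eigenvalue route)
#'
#' Maximizes between-class over within-class scatter.  A within-class scatter
#' matrix with condition number above `cond_max` is refused with a
#' `emg_singular_scatter_error` naming the collinear columns: with exactly
#' duplicated features (IAV/iEMG, AAC/DAMV) in the input this is the expected
#' outcome, and is reported rather than silently patched.  An optional
#' `ridge` (fraction of the mean within-scatter diagonal) exists for users who
#' want a regularized fit anyway.
#'
#' @param X Numeric matrix.
#' @param y Class labels.
#' @param d Latent dimension, `<= n_classes - 1`.
#' @param ridge Ridge fraction added to the within-scatter diagonal (0 = none).
#' @param cond_max Condition-number threshold for declaring singularity.
#' @return An `emg_embedding` with `directions` and a `transform` closure.
#' @export
lda_fit <- function(X, y, d, ridge = 0, cond_max = 1e12) {
  X <- as.matrix(X)
  y <- factor(y)
  if (!is_count(d) || d > nlevels(y) - 1) {
    stop_emg("d must be a positive integer <= n_classes - 1",
             "emg_parameter_error")
  }
  p <- ncol(X)
  mu <- colMeans(X)
  Sw <- matrix(0, p, p)
  Sb <- matrix(0, p, p)
  for (lev in levels(y)) {
    rows <- y == lev
    mc <- colMeans(X[rows, , drop = FALSE])
    Xc <- sweep(X[rows, , drop = FALSE], 2, mc)
    Sw <- Sw + crossprod(Xc)
    Sb <- Sb + sum(rows) * tcrossprod(mc - mu)
  }
  if (ridge > 0) Sw <- Sw + ridge * mean(diag(Sw)) * diag(p)
  ew <- eigen(Sw, symmetric = TRUE)
  vals <- ew$values
  if (vals[1] <= 0 || vals[p] <= 0 || vals[1] / vals[p] > cond_max) {
    qrX <- qr(sweep(X, 2, mu), tol = 1e-10)
    dep <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]] %||%
      qrX$pivot[-seq_len(qrX$rank)]
    stop_emg(sprintf(
      "within-class scatter is numerically singular (collinear columns: %s)",
      paste(dep, collapse = ", ")), "emg_singular_scatter_error")
  }
  Whalf <- ew$vectors %*% (t(ew$vectors) / sqrt(vals))
  M <- Whalf %*% Sb %*% Whalf
  em <- eigen((M + t(M)) / 2, symmetric = TRUE)
  A <- Whalf %*% em$vectors[, seq_len(d), drop = FALSE]
  structure(list(method = "lda", d = d, directions = A,
                 eigenvalues = em$values[seq_len(d)], center = mu,
                 latent = sweep(X, 2, mu) %*% A,
                 transform = function(Xnew) {
                   sweep(as.matrix(Xnew), 2, mu) %*% A
                 }),
            class = "emg_embedding")
}

#' Probabilistic PCA fit by expectation-maximisation
#'
#' Factor model `x = W z + mu + eps` with isotropic Gaussian noise
#' `eps ~ N(0, sigma2 I)`.  The EM updates alternate posterior moments of the
#' latent variables with closed-form updates of `W` and `sigma2`; the marginal
#' log-likelihood is recorded every iteration and is non-decreasing.
#'
#' @param X Numeric matrix.
#' @param d Latent dimension, `< n_cols`.
#' @param tol Convergence tolerance on the log-likelihood increment.
#' @param max_iter Maximum EM iterations (returns with `converged = FALSE`
#'   and a warning if reached).
#' @param seed Seed for the random initialisation of `W`.
#' @return An `emg_embedding` with `W`, `sigma2`, `loglik_trace`, posterior
#'   mean `latent` and a `transform` closure.
#' @export
ppca_em <- function(X, d, tol = 1e-6, max_iter = 500, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (!is_count(d) || d >= p) {
    stop_emg("d must be a positive integer < n_cols", "emg_parameter_error")
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  ss_total <- sum(Xc^2)
  S_tr <- ss_total / n
  W <- with_seed(seed, matrix(rnorm(p * d), p, d) * 0.1)
  sigma2 <- 1
  ll_trace <- numeric(0)
  loglik <- function(W, sigma2) {
    M <- crossprod(W) + sigma2 * diag(d)
    cM <- chol(M)
    logdetC <- (p - d) * log(sigma2) + 2 * sum(log(diag(cM)))
    # tr(C^-1 S) with C = W W' + sigma2 I via Woodbury
    SW <- crossprod(Xc, Xc %*% W) / n         # S W  (p x d)
    trCS <- (S_tr - sum(chol2inv(cM) * crossprod(W, SW))) / sigma2
    -n / 2 * (p * log(2 * pi) + logdetC + trCS)
  }
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ll_trace <- c(ll_trace, loglik(W, sigma2))
    if (it > 1 && abs(ll_trace[it] - ll_trace[it - 1]) < tol) {
      converged <- TRUE
      break
    }
    M <- crossprod(W) + sigma2 * diag(d)
    Minv <- chol2inv(chol(M))
    Ez <- Xc %*% W %*% Minv                   # n x d posterior means
    SumEzz <- n * sigma2 * Minv + crossprod(Ez)
    Wnew <- crossprod(Xc, Ez) %*% chol2inv(chol(SumEzz))
    sigma2 <- (ss_total - 2 * sum(Ez * (Xc %*% Wnew)) +
                 sum(SumEzz * crossprod(Wnew))) / (n * p)
    sigma2 <- max(sigma2, 1e-12)
    W <- Wnew
  }
  if (!converged) {
    warning(sprintf("PPCA EM did not converge in %d iterations", max_iter))
  }
  M <- crossprod(W) + sigma2 * diag(d)
  Minv <- chol2inv(chol(M))
  structure(list(method = "ppca", d = d, W = W, sigma2 = sigma2,
                 loglik_trace = ll_trace, converged = converged, center = mu,
                 latent = Xc %*% W %*% Minv,
                 transform = function(Xnew) {
                   sweep(as.matrix(Xnew), 2, mu) %*% W %*% Minv
                 }),
            class = "emg_embedding")
}

# Squared Euclidean distances between rows.
sqdist <- function(A, B = A) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  pmax(d, 0)
}

#' Gaussian process latent variable model
#'
#' Minimises the negative GP marginal log-likelihood of the (centered) data
#' jointly over latent coordinates and kernel hyperparameters (signal
#' variance, RBF lengthscale, noise variance), by gradient descent with a
#' backtracking line search from a PCA initialisation.  Accepted steps only
#' ever lower the objective, so the recorded trace is non-increasing.  MAP
#' point estimates, not full Bayesian inference.
#'
#' Dense kernel algebra is O(n^3); fits on more than `max_rows` rows must opt
#' in to `subsample`, which fits on a seeded row subset and maps all rows
#' through the out-of-sample `transform` (a ridge regression from data space
#' onto the optimized latents, the model having no parametric inverse map).
#'
#' @param X Numeric matrix.
#' @param d Latent dimension, `< n_cols`.
#' @param kernel `"rbf"` or `"linear"`.
#' @param max_iter Maximum accepted gradient steps.
#' @param subsample Optional number of rows to fit on (seeded draw).
#' @param max_rows Guard above which `subsample` is required.
#' @param seed Seed (subsampling only; the optimisation is deterministic).
#' @return An `emg_embedding` with `latent`, `objective_trace`,
#'   `hyperparameters`, `reconstruct` and `transform` closures.
#' @export
gplvm_fit <- function(X, d, kernel = c("rbf", "linear"), max_iter = 200,
                      subsample = NULL, max_rows = 3000, seed = 1L) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  if (!is_count(d) || d >= ncol(X)) {
    stop_emg("d must be a positive integer < n_cols", "emg_parameter_error")
  }
  if (nrow(X) > max_rows && is.null(subsample)) {
    stop_emg(sprintf(
      "dense GPLVM on %d rows exceeds max_rows = %d; set subsample",
      nrow(X), max_rows), "emg_parameter_error")
  }
  rows_fit <- seq_len(nrow(X))
  if (!is.null(subsample) && subsample < nrow(X)) {
    rows_fit <- sort(with_seed(seed, sample(nrow(X), subsample)))
  }
  Y <- X[rows_fit, , drop = FALSE]
  mu <- colMeans(Y)
  Yc <- sweep(Y, 2, mu)
  n <- nrow(Yc); D <- ncol(Yc)
  S <- tcrossprod(Yc)                       # n x n outer-product matrix

  Z0 <- pca_fit(Y, d)$latent
  sf2_0 <- mean(apply(Yc, 2, stats::var)) + 1e-12
  theta <- list(Z = Z0,
                log_sf2 = log(sf2_0),
                log_l2 = log(mean(sqdist(Z0)) / 2 + 1e-8),
                log_sn2 = log(0.1 * sf2_0))

  kernel_mats <- function(th) {
    sf2 <- exp(th$log_sf2); sn2 <- exp(th$log_sn2)
    if (kernel == "rbf") {
      R2 <- sqdist(th$Z)
      Kf <- sf2 * exp(-0.5 * R2 / exp(th$log_l2))
      list(K = Kf + sn2 * diag(n), Kf = Kf, R2 = R2)
    } else {
      Kf <- sf2 * tcrossprod(th$Z)
      list(K = Kf + sn2 * diag(n), Kf = Kf)
    }
  }
  objective <- function(km) {
    ch <- tryCatch(chol(km$K), error = function(e) NULL)
    if (is.null(ch)) return(list(val = Inf))
    Kinv <- chol2inv(ch)
    val <- 0.5 * (D * 2 * sum(log(diag(ch))) + sum(Kinv * S) +
                    n * D * log(2 * pi))
    list(val = val, Kinv = Kinv)
  }
  gradient <- function(th, km, Kinv) {
    # dF/dK = 0.5 (D Kinv - Kinv S Kinv), symmetric
    KS <- Kinv %*% S %*% Kinv
    G <- 0.5 * (D * Kinv - KS)
    sn2 <- exp(th$log_sn2)
    g <- list()
    if (kernel == "rbf") {
      l2 <- exp(th$log_l2)
      B <- G * km$Kf
      g$Z <- (2 / l2) * (B %*% th$Z - rowSums(B) * th$Z)
      g$log_sf2 <- sum(B)                       # d/dlog sf2: Kf scales with sf2
      g$log_l2 <- sum(B * km$R2) / (2 * l2)
      g$log_sn2 <- sn2 * sum(diag(G))
    } else {
      sf2 <- exp(th$log_sf2)
      g$Z <- 2 * sf2 * (G %*% th$Z)
      g$log_sf2 <- sum(G * km$Kf)
      g$log_sn2 <- sn2 * sum(diag(G))
    }
    g
  }

  km <- kernel_mats(theta)
  ob <- objective(km)
  trace <- ob$val
  step <- 1e-2
  for (it in seq_len(max_iter)) {
    g <- gradient(theta, km, ob$Kinv)
    accepted <- FALSE
    for (try in 1:25) {
      cand <- theta
      cand$Z <- theta$Z - step * g$Z
      cand$log_sf2 <- theta$log_sf2 - step * g$log_sf2
      cand$log_sn2 <- max(theta$log_sn2 - step * g$log_sn2, log(1e-8 * exp(theta$log_sf2)))
      if (kernel == "rbf") cand$log_l2 <- theta$log_l2 - step * g$log_l2
      km_c <- kernel_mats(cand)
      ob_c <- objective(km_c)
      if (is.finite(ob_c$val) && ob_c$val < trace[length(trace)]) {
        theta <- cand; km <- km_c; ob <- ob_c
        trace <- c(trace, ob_c$val)
        step <- step * 1.3
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break
  }
  if (!is.finite(trace[length(trace)])) {
    stop_emg("GPLVM objective became non-finite",
             "emg_optimization_error")
  }

  Z <- theta$Z
  Kinv <- ob$Kinv
  KinvY <- Kinv %*% Yc
  hyp <- list(sf2 = exp(theta$log_sf2), sn2 = exp(theta$log_sn2),
              l2 = if (kernel == "rbf") exp(theta$log_l2) else NA_real_)
  cross_kernel <- function(Znew) {
    if (kernel == "rbf") {
      hyp$sf2 * exp(-0.5 * sqdist(Znew, Z) / hyp$l2)
    } else {
      hyp$sf2 * tcrossprod(Znew, Z)
    }
  }
  # out-of-sample map: ridge regression data space -> latent space
  lam <- 1e-3 * mean(colSums(Yc^2))
  Bmap <- solve(crossprod(Yc) + lam * diag(D), crossprod(Yc, Z))
  transform <- function(Xnew) {
    sweep(as.matrix(Xnew), 2, mu) %*% Bmap
  }
  latent_all <- if (length(rows_fit) < nrow(X)) transform(X) else Z
  structure(list(method = "gplvm", d = d, kernel = kernel, latent = latent_all,
                 latent_fit = Z, rows_fit = rows_fit,
                 objective_trace = trace, hyperparameters = hyp, center = mu,
                 init_objective = trace[1],
                 reconstruct = function(Znew = Z) {
                   sweep(cross_kernel(Znew) %*% KinvY, 2, mu, "+")
                 },
                 transform = transform),
            class = "emg_embedding")
}

#' @export
print.emg_embedding <- function(x, ...) {
  cat(sprintf("emg_embedding [%s]: %d rows -> d = %d\n", x$method,
              nrow(x$latent), x$d))
  if (!is.null(x$explained_variance)) {
    cat("  explained variance:",
        paste(sprintf("%.3f", x$explained_variance), collapse = " "), "\n")
  }
  if (!is.null(x$sigma2)) {
    cat(sprintf("  sigma2 = %.4g after %d EM iterations\n", x$sigma2,
                length(x$loglik_trace)))
  }
  if (!is.null(x$objective_trace)) {
    cat(sprintf("  objective %.4g -> %.4g in %d accepted steps\n",
                x$objective_trace[1], x$objective_trace[length(x$objective_trace)],
                length(x$objective_trace) - 1))
  }
  invisible(x)
}

#' Principal angles between two subspaces
#'
#' @param A,B Matrices whose columns span the two subspaces.
#' @return Numeric vector of angles in radians (ascending).
#' @export
principal_angles <- function(A, B) {
  Qa <- qr.Q(qr(as.matrix(A)))
  Qb <- qr.Q(qr(as.matrix(B)))
  s <- svd(crossprod(Qa, Qb))$d
  acos(pmin(pmax(s, -1), 1))
}

#' ReliefF feature weighting
#'
#' Multiclass ReliefF: every instance contributes nearest-hit penalties and
#' prior-weighted nearest-miss rewards to each feature's weight.  Distances
#' are Manhattan on the (z-scored) inputs; per-feature differences are
#' normalised by the feature range.
#'
#' @param X Numeric matrix, expected z-scored so distances are comparable.
#' @param y Class labels; every class needs `k_neighbors + 1` rows.
#' @param k_neighbors Number of nearest hits/misses per instance and class.
#' @param n_select How many top-weighted columns to select (default 25%).
#' @return An `emg_selection`: `weights`, `selected` (column indices,
#'   descending weight), `method`, parameters.
#' @export
relieff <- function(X, y, k_neighbors = 10, n_select = NULL) {
  X <- as.matrix(X)
  y <- factor(y)
  n <- nrow(X); p <- ncol(X)
  counts <- table(y)
  if (any(counts < k_neighbors + 1)) {
    stop_emg(sprintf("every class needs >= k_neighbors + 1 rows (got min %d)",
                     min(counts)), "emg_parameter_error")
  }
  n_select <- n_select %||% max(1L, ceiling(0.25 * p))
  if (n_select > p) {
    stop_emg("n_select exceeds number of columns", "emg_parameter_error")
  }
  rng <- apply(X, 2, function(col) max(col) - min(col))
  rng[rng < 1e-12] <- 1
  prior <- counts / n
  Wgt <- numeric(p)
  D <- as.matrix(stats::dist(X, method = "manhattan"))
  mean_norm_diff <- function(rows, i) {
    d <- abs(sweep(X[rows, , drop = FALSE], 2, X[i, ]))
    colMeans(sweep(d, 2, rng, "/"))
  }
  for (i in seq_len(n)) {
    ci <- as.character(y[i])
    hits <- which(y == y[i]); hits <- hits[hits != i]
    hits <- hits[order(D[i, hits])][seq_len(k_neighbors)]
    Wgt <- Wgt - mean_norm_diff(hits, i) / n
    for (cl in levels(y)) {
      if (cl == ci) next
      miss <- which(y == cl)
      miss <- miss[order(D[i, miss])][seq_len(k_neighbors)]
      wc <- prior[[cl]] / (1 - prior[[ci]])
      Wgt <- Wgt + wc * mean_norm_diff(miss, i) / n
    }
  }
  names(Wgt) <- colnames(X)
  ord <- order(-Wgt, seq_len(p))
  structure(list(method = "relieff", weights = Wgt,
                 selected = ord[seq_len(n_select)],
                 k_neighbors = k_neighbors, n_select = n_select),
            class = "emg_selection")
}

#' L1-penalised (Lasso) feature selection
#'
#' One-vs-rest L1-penalised logistic regressions over a shared lambda grid;
#' the penalty is chosen by cross-validated classification accuracy of the
#' argmax-over-classes linear scores (ties resolved toward the sparser
#' model), and the selection is the union of columns with a nonzero
#' coefficient in any class at the chosen penalty.
#'
#' @param X Numeric matrix (>= 2 columns).
#' @param y Class labels (>= 2 classes).
#' @param lambda_grid Optional decreasing penalty grid; defaults to the
#'   glmnet path of the first one-vs-rest problem.
#' @param cv_folds Folds for the accuracy criterion.
#' @param seed Fold seed.
#' @return An `emg_selection`: `coefficients` (column x class matrix at the
#'   chosen lambda), `selected`, `lambda`, `cv_accuracy` per lambda.
#' @export
lasso_select <- function(X, y, lambda_grid = NULL, cv_folds = 5, seed = 1L) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) < 2) stop_emg(">= 2 classes required", "emg_input_error")
  if (is.null(lambda_grid)) {
    f0 <- glmnet::glmnet(X, as.integer(y == levels(y)[1]),
                         family = "binomial", nlambda = 25,
                         lambda.min.ratio = 0.01, standardize = FALSE)
    lambda_grid <- f0$lambda
  }
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  folds <- stratified_folds(y, cv_folds, seed)
  nl <- length(lambda_grid)
  acc <- matrix(0, cv_folds, nl)
  for (f in seq_len(cv_folds)) {
    tr <- folds != f
    scores <- array(0, c(sum(!tr), nlevels(y), nl))
    for (ci in seq_len(nlevels(y))) {
      fit <- glmnet::glmnet(X[tr, , drop = FALSE],
                            as.integer(y[tr] == levels(y)[ci]),
                            family = "binomial", lambda = lambda_grid,
                            standardize = FALSE, maxit = 2e4)
      pr <- predict(fit, X[!tr, , drop = FALSE], s = lambda_grid,
                    type = "link")
      scores[, ci, seq_len(ncol(pr))] <- pr
    }
    for (li in seq_len(nl)) {
      pred <- levels(y)[max.col(scores[, , li, drop = FALSE][, , 1],
                                ties.method = "first")]
      acc[f, li] <- mean(pred == as.character(y[!tr]))
    }
  }
  macc <- colMeans(acc)
  best <- which(macc == max(macc))[1]  # grid is descending: sparsest winner
  lambda <- lambda_grid[best]
  coefs <- sapply(levels(y), function(lev) {
    fit <- glmnet::glmnet(X, as.integer(y == lev), family = "binomial",
                          lambda = lambda_grid, standardize = FALSE,
                          maxit = 2e4)
    as.numeric(coef(fit, s = lambda))[-1]  # drop intercept
  })
  rownames(coefs) <- colnames(X)
  selected <- which(rowSums(abs(coefs) > 0) > 0)
  if (length(selected) == 0) {
    warning("all coefficients zero at the chosen lambda; falling back to the smallest lambda")
    lambda <- min(lambda_grid)
    coefs <- sapply(levels(y), function(lev) {
      fit <- glmnet::glmnet(X, as.integer(y == lev), family = "binomial",
                            lambda = lambda_grid, standardize = FALSE,
                            maxit = 2e4)
      as.numeric(coef(fit, s = lambda))[-1]
    })
    rownames(coefs) <- colnames(X)
    selected <- which(rowSums(abs(coefs) > 0) > 0)
  }
  structure(list(method = "lasso", coefficients = coefs,
                 selected = unname(selected), lambda = lambda,
                 lambda_grid = lambda_grid, cv_accuracy = macc),
            class = "emg_selection")
}

#' @export
print.emg_selection <- function(x, ...) {
  cat(sprintf("emg_selection [%s]: %d column(s) selected\n", x$method,
              length(x$selected)))
  invisible(x)
}

# Build the per-fold reduction closure used by evaluate_cv.
reduction_closure <- function(method, params, seed) {
  switch(method,
    none = NULL,
    pca = function(Xtr, ytr) {
      d <- params$d %||% pca_dim_for_variance(Xtr, params$var_target %||% 0.95)
      pca_fit(Xtr, d)
    },
    lda = function(Xtr, ytr) {
      d <- min(params$d %||% (nlevels(factor(ytr)) - 1),
               nlevels(factor(ytr)) - 1)
      lda_fit(Xtr, ytr, d, ridge = params$ridge %||% 0)
    },
    ppca = function(Xtr, ytr) {
      d <- params$d %||% pca_dim_for_variance(Xtr, params$var_target %||% 0.95)
      suppressWarnings(ppca_em(Xtr, d, max_iter = params$max_iter %||% 100,
                               seed = seed))
    },
    gplvm = function(Xtr, ytr) {
      gplvm_fit(Xtr, d = min(params$d %||% 10, ncol(Xtr) - 1),
                kernel = params$kernel %||% "rbf",
                max_iter = params$max_iter %||% 50,
                subsample = params$subsample %||% min(nrow(Xtr), 300),
                seed = seed)
    },
    relieff = function(Xtr, ytr) {
      mask <- relieff(Xtr, ytr, k_neighbors = params$k_neighbors %||% 10,
                      n_select = params$n_select)
      list(transform = function(Xnew) Xnew[, mask$selected, drop = FALSE])
    },
    lasso = function(Xtr, ytr) {
      mask <- lasso_select(Xtr, ytr, lambda_grid = params$lambda_grid,
                           cv_folds = params$cv_folds %||% 5, seed = seed)
      list(transform = function(Xnew) Xnew[, mask$selected, drop = FALSE])
    },
    stop_emg(sprintf("unknown reduction method '%s'", method),
             "emg_parameter_error")
  )
}

#' Cross-validated accuracy of the ANN after a reduction method
#'
#' The reduction is fit inside each training fold (after fold-local
#' z-scoring) and applied to the held-out fold, then the ANN is trained on
#' the reduced representation.  Wall-clock seconds are recorded for the
#' comparison tables but are informational only.
#'
#' @param fm An `emg_feature_matrix` or numeric matrix.
#' @param method One of `"none"`, `"pca"`, `"lda"`, `"ppca"`, `"gplvm"`,
#'   `"relieff"`, `"lasso"`.
#' @param method_params List of method-specific parameters (`d`,
#'   `var_target`, `ridge`, `n_select`, `lambda_grid`, `max_iter`, ...).
#' @param cfg [ann_config()].
#' @param labels Labels when `fm` is a bare matrix.
#' @param k,seed,folds Passed to [evaluate_cv()].
#' @return List with `report` (an `emg_cv_report`), `seconds`, `method`.
#' @export
evaluate_reduction <- function(fm, method = "none", method_params = list(),
                               cfg = ann_config(profile = "fast"),
                               labels = NULL, k = 5, seed = 1L,
                               folds = NULL) {
  X <- if (inherits(fm, "emg_feature_matrix")) fm$values else as.matrix(fm)
  y <- labels %||% fm$labels
  red <- reduction_closure(method, method_params, seed)
  t0 <- proc.time()[["elapsed"]]
  report <- evaluate_cv(X, y, cfg, k = k, seed = seed, folds = folds,
                        reduction = red)
  list(report = report, seconds = proc.time()[["elapsed"]] - t0,
       method = method, method_params = method_params)
}

#' Compare all reduction methods on one dataset
#'
#' Runs [evaluate_reduction()] for the identity route and the six methods,
#' sharing one fold assignment; failures (LDA on collinear features) are
#' caught and reported as rows with `error` filled in, mirroring how a
#' singular within-class scatter is a result, not a crash.
#'
#' @param fm An `emg_feature_matrix`.
#' @param methods Methods to run.
#' @param cfg,k,seed Passed through.
#' @param method_params Named list of per-method parameter lists.
#' @return Data frame: method, mean_accuracy, sd_accuracy, seconds, error.
#' @export
compare_reductions <- function(fm,
                               methods = c("none", "pca", "lda", "ppca",
                                           "gplvm", "relieff", "lasso"),
                               cfg = ann_config(profile = "fast"),
                               k = 5, seed = 1L, method_params = list()) {
  folds <- stratified_folds(fm$labels, k, seed)
  rows <- lapply(methods, function(m) {
    res <- tryCatch(
      evaluate_reduction(fm, m, method_params[[m]] %||% list(), cfg,
                         k = k, seed = seed, folds = folds),
      error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(method = m, mean_accuracy = NA_real_, sd_accuracy = NA_real_,
                 seconds = NA_real_, error = conditionMessage(res),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(method = m, mean_accuracy = res$report$mean_accuracy,
                 sd_accuracy = res$report$sd_accuracy, seconds = res$seconds,
                 error = "", stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
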