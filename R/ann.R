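# The movement classifier: a feed-forward network with ReLU hidden layers and
# a softmax output, trained with Adam on cross-entropy for a fixed number of
# epochs (no early stopping, so the stated iteration budget is honoured).
# Training runs in compiled code; this file owns configuration, the stratified
# cross-validation harness and the no-leakage contract (scalers fit on the
# training fold only).

#' ANN classifier configuration
#'
#' The reference architecture is three hidden layers of 20 ReLU units trained
#' for 1000 epochs.  The `fast` profile (150 epochs) exists for desk-scale
#' runs such as exhaustive subset search; architecture is unchanged.
#'
#' @param hidden_layers Number of hidden layers.
#' @param neurons_per_layer Units per hidden layer.
#' @param max_iter Training epochs (full passes over the data).
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size; the effective batch is
#'   `min(n_rows, batch_size)`.
#' @param seed Integer seed; training is bit-deterministic given it.
#' @param profile Convenience switch: `"paper"` keeps `max_iter`, `"fast"`
#'   lowers it to 150.
#' @return A list of class `emg_ann_config`.
#' @export
ann_config <- function(hidden_layers = 3, neurons_per_layer = 20,
                       max_iter = 1000, learning_rate = 1e-3,
                       batch_size = 128, seed = 1L,
                       profile = c("paper", "fast")) {
  profile <- match.arg(profile)
  if (profile == "fast") max_iter <- min(max_iter, 150)
  if (!is_count(hidden_layers) || !is_count(neurons_per_layer) ||
      !is_count(max_iter)) {
    stop_emg("layers, neurons and max_iter must be positive integers",
             "emg_parameter_error")
  }
  structure(list(hidden_layers = as.integer(hidden_layers),
                 neurons_per_layer = as.integer(neurons_per_layer),
                 max_iter = as.integer(max_iter),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), profile = profile),
            class = "emg_ann_config")
}

#' Train the ANN classifier
#'
#' @param X Numeric matrix of z-scored feature rows.
#' @param y Class labels (factor or coercible).
#' @param cfg [ann_config()].
#' @return An `emg_ann_model` exposing `predict(model, X)`.
#' @export
train_ann <- function(X, y, cfg = ann_config()) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) < 2) {
    stop_emg("training needs at least 2 classes", "emg_training_error")
  }
  if (nrow(X) != length(y)) {
    stop_emg("X rows and labels disagree", "emg_input_error")
  }
  hidden <- rep(cfg$neurons_per_layer, cfg$hidden_layers)
  fit <- ann_train_cpp(X, as.integer(y) - 1L, nlevels(y), hidden,
                       cfg$max_iter, cfg$learning_rate,
                       min(nrow(X), cfg$batch_size), cfg$seed)
  structure(list(W = fit$W, b = fit$b, levels = levels(y), cfg = cfg),
            class = "emg_ann_model")
}

#' @export
predict.emg_ann_model <- function(object, newdata, type = c("class", "prob"),
                                  ...) {
  type <- match.arg(type)
  P <- ann_forward_cpp(object$W, object$b, as.matrix(newdata))
  colnames(P) <- object$levels
  if (type == "prob") return(P)
  factor(object$levels[max.col(P, ties.method = "first")],
         levels = object$levels)
}

#' @export
print.emg_ann_model <- function(x, ...) {
  cat(sprintf("emg_ann_model: %d->%s->%d, %d classes\n",
              nrow(x$W[[1]]),
              paste(rep(x$cfg$neurons_per_layer, x$cfg$hidden_layers),
                    collapse = "-"),
              length(x$levels), length(x$levels)))
  invisible(x)
}

#' Stratified fold assignment
#'
#' Each class's rows are shuffled (seeded) and dealt round-robin over `k`
#' folds, so fold class proportions match the data as closely as possible.
#'
#' @param y Class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector in `1..k`, one entry per row.
#' @export
stratified_folds <- function(y, k = 5, seed = 1L) {
  y <- factor(y)
  counts <- table(y)
  if (any(counts < k)) {
    stop_emg(sprintf("every class needs >= k rows (k = %d; smallest class has %d)",
                     k, min(counts)), "emg_fold_error")
  }
  folds <- integer(length(y))
  with_seed(seed, {
    for (lev in levels(y)) {
      idx <- sample(which(y == lev))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Cross-validated accuracy of the ANN
#'
#' Stratified k-fold cross-validation.  Inside each fold the z-scaler (and,
#' when `reduction` is given, the reduction itself) is fit on the training
#' rows only and applied to the held-out rows, so no test statistics leak into
#' training.
#'
#' @param X Feature rows (not yet scaled).
#' @param y Class labels.
#' @param cfg [ann_config()].
#' @param k Number of folds.
#' @param seed Seed controlling fold assignment and per-fold training.
#' @param folds Optional precomputed fold assignment (overrides `seed` for
#'   the partition); used to share one partition across many evaluations.
#' @param reduction Optional function `(X_train, y_train) -> list(transform =
#'   function(X) ...)` fit per fold before the ANN.
#' @param return_models Keep the per-fold models in the report.
#' @return An `emg_cv_report`: `fold_accuracies`, `mean_accuracy`,
#'   `sd_accuracy`, `n_samples`, `n_classes`, `folds`, `train_seconds`.
#' @export
evaluate_cv <- function(X, y, cfg = ann_config(), k = 5, seed = 1L,
                        folds = NULL, reduction = NULL,
                        return_models = FALSE) {
  X <- as.matrix(X)
  y <- factor(y)
  folds <- folds %||% stratified_folds(y, k, seed)
  k_eff <- max(folds)
  acc <- numeric(k_eff)
  models <- if (return_models) vector("list", k_eff) else NULL
  t0 <- proc.time()[["elapsed"]]
  for (f in seq_len(k_eff)) {
    tr <- folds != f
    sc <- suppressWarnings(zscore_fit(X, which(tr)))
    Xtr <- zscore_apply(X[tr, , drop = FALSE], sc)
    Xte <- zscore_apply(X[!tr, , drop = FALSE], sc)
    if (!is.null(reduction)) {
      red <- reduction(Xtr, y[tr])
      Xtr <- red$transform(Xtr)
      Xte <- red$transform(Xte)
    }
    cfg_f <- cfg
    cfg_f$seed <- derive_seed(cfg$seed, f)
    model <- train_ann(Xtr, droplevels(y[tr]), cfg_f)
    pred <- predict(model, Xte)
    acc[f] <- mean(as.character(pred) == as.character(y[!tr]))
    if (return_models) models[[f]] <- model
  }
  structure(list(fold_accuracies = acc, mean_accuracy = mean(acc),
                 sd_accuracy = stats::sd(acc),
                 n_samples = nrow(X), n_classes = nlevels(y), folds = folds,
                 train_seconds = proc.time()[["elapsed"]] - t0,
                 models = models),
            class = "emg_cv_report")
}

#' @export
print.emg_cv_report <- function(x, ...) {
  cat(sprintf("emg_cv_report: mean accuracy %.3f (sd %.3f) over %d folds, n = %d, %d classes [%.1fs]\n",
              x$mean_accuracy, x$sd_accuracy, length(x$fold_accuracies),
              x$n_samples, x$n_classes, x$train_seconds))
  invisible(x)
}
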