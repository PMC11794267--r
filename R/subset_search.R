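# Exhaustive wrapper feature selection: every k-subset of the retained
# features is evaluated by the ANN under one shared fold assignment, so the
# accuracies are directly comparable; the report keeps the full sorted table
# plus the top 10.  C(16, k) for k = 2..5 is 120 / 560 / 1820 / 4368
# evaluations, which is why the `fast` ANN profile exists.

#' Enumerate all k-subsets of a feature list
#'
#' Lexicographic order over the input ordering; `choose(n, k)` subsets.
#'
#' @param features Ordered character vector.
#' @param k Subset size, `1 <= k <= length(features)`.
#' @return List of character vectors.
#' @export
enumerate_subsets <- function(features, k) {
  n <- length(features)
  if (!is_count(k) || k > n) {
    stop_emg("k must be a positive integer <= length(features)",
             "emg_parameter_error")
  }
  idx <- utils::combn(n, k)
  lapply(seq_len(ncol(idx)), function(j) features[idx[, j]])
}

#' Exhaustively evaluate all k-feature subsets
#'
#' Every subset's columns (that subset's features across all channels) are
#' scored with [evaluate_cv()] under a single fold assignment derived from
#' `seed`.  Results are sorted by mean accuracy (descending; ties broken by
#' lexicographic subset order).  An optional JSON-lines checkpoint file makes
#' the search resumable: completed subsets are read back and skipped, and the
#' final report is identical to an uninterrupted run.
#'
#' @param fm An `emg_feature_matrix` containing the retained features.
#' @param retained Character vector of feature names to search over.
#' @param k Subset size.
#' @param cfg [ann_config()].
#' @param seed Seed for the shared fold assignment.
#' @param cv_k Number of CV folds.
#' @param checkpoint Optional path to a JSON-lines checkpoint file.
#' @return An `emg_search_report`: `k`, `n_evaluated`, `results` (data frame
#'   sorted by accuracy), `top10`, `accuracy_range`, `folds`.
#' @export
exhaustive_search <- function(fm, retained, k, cfg = ann_config(profile = "fast"),
                              seed = 1L, cv_k = 5, checkpoint = NULL) {
  stopifnot(inherits(fm, "emg_feature_matrix"))
  missing <- setdiff(retained, fm$feature_names)
  if (length(missing)) {
    stop_emg(sprintf("retained features absent from matrix: %s",
                     paste(missing, collapse = ", ")), "emg_catalog_error")
  }
  subsets <- enumerate_subsets(retained, k)
  keys <- vapply(subsets, paste, "", collapse = "+")
  folds <- stratified_folds(fm$labels, cv_k, seed)

  done <- list()
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    lines <- readLines(checkpoint, warn = FALSE)
    for (ln in lines) {
      rec <- tryCatch(jsonlite::fromJSON(ln), error = function(e) NULL)
      if (!is.null(rec) && rec$key %in% keys) done[[rec$key]] <- rec
    }
  }

  rows <- vector("list", length(subsets))
  for (j in seq_along(subsets)) {
    key <- keys[j]
    if (!is.null(done[[key]])) {
      rec <- done[[key]]
      rows[[j]] <- data.frame(subset = key, mean_accuracy = rec$mean,
                              sd_accuracy = rec$sd, stringsAsFactors = FALSE)
      next
    }
    sub_fm <- select_features(fm, subsets[[j]])
    cv <- tryCatch(
      evaluate_cv(sub_fm$values, sub_fm$labels, cfg, k = cv_k, seed = seed,
                  folds = folds),
      error = function(e) {
        stop_emg(sprintf("evaluation failed for subset {%s}: %s", key,
                         conditionMessage(e)), "emg_search_error")
      })
    rows[[j]] <- data.frame(subset = key, mean_accuracy = cv$mean_accuracy,
                            sd_accuracy = cv$sd_accuracy,
                            stringsAsFactors = FALSE)
    if (!is.null(checkpoint)) {
      cat(jsonlite::toJSON(list(key = key, mean = cv$mean_accuracy,
                                sd = cv$sd_accuracy), auto_unbox = TRUE,
                           digits = NA),
          "\n", sep = "", file = checkpoint, append = TRUE)
    }
  }
  results <- do.call(rbind, rows)
  # descending accuracy; ties broken by lexicographic (= enumeration) order
  ord <- order(-results$mean_accuracy, seq_len(nrow(results)))
  results <- results[ord, , drop = FALSE]
  rownames(results) <- NULL
  structure(list(k = k, n_evaluated = nrow(results), results = results,
                 top10 = utils::head(results, 10),
                 accuracy_range = range(results$mean_accuracy),
                 folds = folds, seed = seed),
            class = "emg_search_report")
}

#' @export
print.emg_search_report <- function(x, ...) {
  cat(sprintf("emg_search_report: %d subsets of size %d; accuracy %.3f-%.3f\n",
              x$n_evaluated, x$k, x$accuracy_range[1], x$accuracy_range[2]))
  print(utils::head(x$top10, 5))
  invisible(x)
}

#' Compare search reports across subset sizes
#'
#' Takes the top-10 mean accuracies of each report as that size's replicate
#' group, runs a one-way ANOVA across groups and flags whether the group
#' means are non-decreasing in k.
#'
#' @param reports List of `emg_search_report` objects (>= 2).
#' @return An `emg_size_comparison`: `k_values`, `group_means`, `anova`
#'   ([anova_oneway()] result), `monotone_increasing`.
#' @export
compare_set_sizes <- function(reports) {
  if (!is.list(reports) || length(reports) < 2 ||
      !all(vapply(reports, inherits, TRUE, "emg_search_report"))) {
    stop_emg("need >= 2 search reports", "emg_parameter_error")
  }
  ks <- vapply(reports, `[[`, 0, "k")
  reports <- reports[order(ks)]
  ks <- sort(ks)
  groups <- lapply(reports, function(r) r$top10$mean_accuracy)
  if (any(lengths(groups) < 2)) {
    stop_emg("each report needs >= 2 top-set accuracies",
             "emg_parameter_error")
  }
  names(groups) <- paste0("k", ks)
  means <- vapply(groups, mean, 0)
  structure(list(k_values = ks, group_means = means,
                 anova = anova_oneway(groups),
                 monotone_increasing = all(diff(means) >= 0)),
            class = "emg_size_comparison")
}

#' @export
print.emg_size_comparison <- function(x, ...) {
  cat("emg_size_comparison:\n")
  print(round(x$group_means, 4))
  cat(sprintf("  ANOVA F = %.3f on (%d, %d) df, p = %.4g; monotone: %s\n",
              x$anova$F, x$anova$df_between, x$anova$df_within, x$anova$p,
              x$monotone_increasing))
  invisible(x)
}

#' Write a search report CSV (rank, subset, mean, sd)
#'
#' @param report An `emg_search_report`.
#' @param path Output CSV path.
#' @param top_only Write only the top 10 rows.
#' @export
write_search_csv <- function(report, path, top_only = FALSE) {
  df <- if (top_only) report$top10 else report$results
  df <- cbind(rank = seq_len(nrow(df)), df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
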