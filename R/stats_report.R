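# One-way ANOVA (classical between/within sums of squares) and the pipeline
# report bundle.

#' One-way analysis of variance
#'
#' Classical fixed-effects F test: the between-group mean square over the
#' within-group mean square, with a central-F p value.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each >= 2
#'   values; within-group variance must not be zero everywhere).
#' @return An `emg_anova`: `group_means`, `F`, `df_between`, `df_within`,
#'   `p`, `ss_between`, `ss_within`.
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop_emg("need >= 2 groups", "emg_parameter_error")
  }
  if (any(lengths(groups) < 2)) {
    stop_emg("each group needs >= 2 values", "emg_parameter_error")
  }
  all_x <- unlist(groups)
  if (!all(is.finite(all_x))) {
    stop_emg("groups must be finite numeric", "emg_parameter_error")
  }
  grand <- mean(all_x)
  means <- vapply(groups, mean, 0)
  ns <- lengths(groups)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  dfb <- length(groups) - 1
  dfw <- sum(ns) - length(groups)
  if (ssw <= 0) {
    if (ssb <= 0) {
      # all values identical everywhere: no evidence of any difference
      return(structure(list(group_means = means, F = 0, df_between = dfb,
                            df_within = dfw, p = 1, ss_between = ssb,
                            ss_within = ssw), class = "emg_anova"))
    }
    stop_emg("within-group variance is zero; F is undefined",
             "emg_parameter_error")
  }
  Fval <- (ssb / dfb) / (ssw / dfw)
  structure(list(group_means = means, F = Fval, df_between = dfb,
                 df_within = dfw, p = stats::pf(Fval, dfb, dfw,
                                                lower.tail = FALSE),
                 ss_between = ssb, ss_within = ssw),
            class = "emg_anova")
}

#' @export
print.emg_anova <- function(x, ...) {
  cat(sprintf("emg_anova: F = %.4f on (%d, %d) df, p = %.4g\n",
              x$F, x$df_between, x$df_within, x$p))
  invisible(x)
}

#' Assemble a self-contained pipeline report directory
#'
#' Writes whatever stage results are supplied; absent stages are flagged
#' `"not run"` in the JSON summary rather than treated as errors.  With the
#' same inputs and config the emitted tables are byte-identical across runs.
#'
#' @param out_dir Directory to create.
#' @param config List snapshot of run parameters (seeds included).
#' @param ranking Optional `emg_feature_ranking`.
#' @param reductions Optional data frame from [compare_reductions()].
#' @param searches Optional list of `emg_search_report` objects.
#' @param anova Optional `emg_anova` or `emg_size_comparison`.
#' @return `out_dir`, invisibly.
#' @export
build_report <- function(out_dir, config = list(), ranking = NULL,
                         reductions = NULL, searches = NULL, anova = NULL) {
  if (is.null(ranking) && is.null(reductions) && is.null(searches) &&
      is.null(anova)) {
    stop_emg("at least one stage result is required", "emg_parameter_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  summary <- list(stages = list())

  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  note("config snapshot written")

  if (!is.null(ranking)) {
    write_ranking_csv(ranking, file.path(out_dir, "ranking.csv"))
    summary$stages$ranking <- list(
      status = "ok", retained = ranking$retained,
      threshold = ranking$threshold)
    note("ranking: %d retained of %d", length(ranking$retained),
         length(ranking$accuracy))
  } else {
    summary$stages$ranking <- list(status = "not run")
  }

  if (!is.null(reductions)) {
    utils::write.csv(reductions, file.path(out_dir, "reductions.csv"),
                     row.names = FALSE, quote = TRUE)
    summary$stages$reductions <- list(
      status = "ok", methods = reductions$method,
      failed = reductions$method[reductions$error != ""])
    note("reductions: %d methods (%d failed)", nrow(reductions),
         sum(reductions$error != ""))
  } else {
    summary$stages$reductions <- list(status = "not run")
  }

  if (!is.null(searches)) {
    for (rep in searches) {
      write_search_csv(rep, file.path(out_dir,
                                      sprintf("search_k%d.csv", rep$k)))
    }
    summary$stages$search <- list(
      status = "ok", k_values = vapply(searches, `[[`, 0, "k"),
      n_evaluated = vapply(searches, `[[`, 0, "n_evaluated"))
    note("search: %d set sizes", length(searches))
  } else {
    summary$stages$search <- list(status = "not run")
  }

  if (!is.null(anova)) {
    an <- if (inherits(anova, "emg_size_comparison")) anova$anova else anova
    payload <- list(F = an$F, df_between = an$df_between,
                    df_within = an$df_within, p = an$p,
                    group_means = as.list(an$group_means))
    if (inherits(anova, "emg_size_comparison")) {
      payload$monotone_increasing <- anova$monotone_increasing
    }
    jsonlite::write_json(payload, file.path(out_dir, "anova.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    summary$stages$anova <- list(status = "ok")
    note("anova: F = %.4f", an$F)
  } else {
    summary$stages$anova <- list(status = "not run")
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(out_dir)
}
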