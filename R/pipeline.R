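# End-to-end desk-scale driver: synthesize -> preprocess -> segment ->
# extract -> rank -> reduce -> search -> compare -> report.  Every stage is
# the exported function documented in its own module; this file only wires
# them together and keeps the run reproducible from one seed.

#' Run the full synthetic pipeline
#'
#' Generates `n_subjects` synthetic recordings, notch- and bandpass-filters
#' them, cuts 250 ms / 50% overlap windows, extracts the full 41-feature
#' catalog, ranks features on the first subject's data, restricts to the
#' retained set, compares the reduction methods, exhaustively searches
#' subsets of sizes `search_k` over the top `search_features` retained
#' features, compares the set sizes by ANOVA and (optionally) writes a report
#' directory.
#'
#' The defaults are a deliberately scaled-down session (fewer repetitions and
#' subjects than a real acquisition) so the whole run fits in minutes on one
#' CPU; the stages themselves are unchanged by the scaling.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Optional report directory (see [build_report()]).
#' @param profile `"fast"` (150 epochs) or `"paper"` (1000 epochs).
#' @param n_subjects,n_reps,n_channels Synthetic session shape.
#' @param threshold Ranking elimination threshold.
#' @param search_features Number of top-ranked features fed to the
#'   exhaustive search.
#' @param search_k Subset sizes to search.
#' @param reduction_methods Methods passed to [compare_reductions()].
#' @return List with `ranking`, `retained_fm`, `reductions`, `searches`,
#'   `size_comparison`, `config`.
#' @export
run_pipeline <- function(seed = 1L, out_dir = NULL,
                         profile = c("fast", "paper"),
                         n_subjects = 2, n_reps = 3, n_channels = 12,
                         threshold = 0.85, search_features = 6,
                         search_k = 2:5,
                         reduction_methods = c("none", "pca", "lda", "ppca",
                                               "gplvm", "relieff", "lasso")) {
  profile <- match.arg(profile)
  cfg <- ann_config(profile = profile, seed = derive_seed(seed, 1))

  fms <- lapply(seq_len(n_subjects), function(s) {
    sc <- synth_config(n_channels = n_channels, n_reps = n_reps,
                       powerline_amp = 0.2, seed = derive_seed(seed, 10 + s))
    rec <- generate_recording(sc, sprintf("S%d", s))
    rec <- notch_filter(rec)
    rec <- bandpass_filter(rec)
    extract_features(segment_recording(rec))
  })
  fm_all <- combine_feature_matrices(fms)

  ranking <- rank_features(fms[[1]], cfg, threshold = threshold,
                           seed = derive_seed(seed, 2))
  fm_ret <- apply_retention(fm_all, ranking)

  reductions <- compare_reductions(fm_ret, methods = reduction_methods,
                                   cfg = cfg, seed = derive_seed(seed, 3))

  search_set <- utils::head(ranking$retained, search_features)
  searches <- lapply(search_k, function(k) {
    exhaustive_search(fm_ret, search_set, k, cfg,
                      seed = derive_seed(seed, 4))
  })
  size_cmp <- if (length(searches) >= 2) compare_set_sizes(searches) else NULL

  config <- list(seed = seed, profile = profile, n_subjects = n_subjects,
                 n_reps = n_reps, n_channels = n_channels,
                 threshold = threshold, search_features = search_set,
                 search_k = search_k, ann = unclass(cfg))
  if (!is.null(out_dir)) {
    build_report(out_dir, config = config, ranking = ranking,
                 reductions = reductions, searches = searches,
                 anova = size_cmp)
  }
  list(ranking = ranking, retained_fm = fm_ret, reductions = reductions,
       searches = searches, size_comparison = size_cmp, config = config)
}
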