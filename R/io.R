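# On-disk formats: a recording is a TSV sample matrix (samples x channels,
# header = channel names) plus a JSON sidecar (<path>.json) holding fs,
# subject_id and the annotation table.  Feature matrices round-trip to CSV with
# "ch{c}_{FEAT}" column headers and a final `label` column.

#' Write / read a recording
#'
#' `write_recording()` stores the signal as a tab-separated samples-by-channels
#' matrix at `path` and the metadata (sampling rate, subject, annotations) in a
#' JSON sidecar at `paste0(path, ".json")`.  `read_recording()` reverses it;
#' the pair round-trips annotations exactly and signal values to double
#' printing precision (~1e-9 relative).
#'
#' @param rec An `emg_recording`.
#' @param path File path for the TSV matrix (sidecar added automatically).
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns an `emg_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "emg_recording"))
  mat <- t(rec$signal)
  colnames(mat) <- rownames(rec$signal) %||% sprintf("ch%d", seq_len(nrow(rec$signal)))
  utils::write.table(format(mat, digits = 15, trim = TRUE, scientific = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(fs = rec$fs, subject_id = rec$subject_id,
                  annotations = rec$annotations)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) {
    stop_emg(sprintf("missing sidecar '%s'", sidecar_path), "emg_format_error")
  }
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (is.null(meta$fs)) {
    stop_emg("sidecar does not declare fs", "emg_format_error")
  }
  mat <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                     check.names = FALSE))
  signal <- t(mat)
  ann <- meta$annotations
  if (is.null(ann) || length(ann) == 0 || NROW(ann) == 0) {
    ann <- data.frame(onset = integer(0), offset = integer(0),
                      movement = character(0), repetition = integer(0),
                      stringsAsFactors = FALSE)
  } else {
    ann <- as.data.frame(ann, stringsAsFactors = FALSE)
  }
  new_recording(signal, meta$fs, ann, meta$subject_id %||% "unknown")
}

#' Write / read a feature matrix as CSV
#'
#' Columns are ordered channel-major (`ch1_IEMG, ch1_RMS, ..., ch2_IEMG, ...`)
#' with the class label as the final `label` column; the ordering is
#' bit-stable so repeated writes of the same object are byte-identical.
#'
#' @param fm An `emg_feature_matrix`.
#' @param path CSV path.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "emg_feature_matrix"))
  df <- as.data.frame(fm$values, check.names = FALSE)
  df$label <- as.character(fm$labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- factor(df$label)
  values <- as.matrix(df[setdiff(names(df), "label")])
  meta <- parse_feature_columns(colnames(values))
  new_feature_matrix(values, labels, meta$channels, meta$features)
}

parse_feature_columns <- function(cols) {
  m <- regmatches(cols, regexec("^ch([0-9]+)_(.+)$", cols))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop_emg("feature columns must be named ch{c}_{FEAT}", "emg_format_error")
  }
  channels <- unique(as.integer(vapply(m, `[`, "", 2L)))
  features <- unique(vapply(m, `[`, "", 3L))
  list(channels = channels, features = features)
}
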