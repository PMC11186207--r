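#' Read a PU dataset from a delimited file
#'
#' Expects a header row, one sample per row, a sample-id column, numeric
#' feature columns, a 0/1 P/U label column and optionally a 0/1 ground
#' truth column. Every column other than the named id/label columns is
#' treated as a feature.
#'
#' @param path CSV or TSV file path (delimiter inferred from extension;
#'   `.tsv`/`.txt` read as tab-separated).
#' @param pu_col name of the P/U label column (default `"pu_label"`).
#' @param truth_col name of the optional ground-truth column (default
#'   `"truth_label"`; silently skipped when absent).
#' @param id_col name of the sample-id column (default `"sample_id"`;
#'   when absent, row numbers are used).
#' @return a [pu_dataset()].
#' @export
read_pu_csv <- function(path, pu_col = "pu_label",
                        truth_col = "truth_label", id_col = "sample_id") {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 stringsAsFactors = FALSE)
  if (!pu_col %in% names(df))
    stop("P/U label column '", pu_col, "' not found in ", path)
  ids <- if (id_col %in% names(df)) as.character(df[[id_col]]) else
    sprintf("s%04d", seq_len(nrow(df)))
  truth <- if (truth_col %in% names(df)) df[[truth_col]] else NULL
  drop <- intersect(c(pu_col, truth_col, id_col), names(df))
  feats <- as.matrix(df[, setdiff(names(df), drop), drop = FALSE])
  storage.mode(feats) <- "double"
  rownames(feats) <- ids
  pu_dataset(feats, df[[pu_col]], truth)
}

#' Write a PU dataset to CSV
#'
#' Writes columns `sample_id`, the features, `pu_label` and (when ground
#' truth is present) `truth_label`. When `config` is supplied, a sidecar
#' YAML file (same path with extension `.yaml`) records the full
#' generation configuration and seed for audit.
#'
#' @param data a [pu_dataset()].
#' @param path output CSV path.
#' @param config optional [synthetic_config()] (or any list) to record in
#'   the sidecar YAML.
#' @param n_kp optional known-positive count to record alongside the
#'   config.
#' @return `path`, invisibly.
#' @export
write_pu_csv <- function(data, path, config = NULL, n_kp = NULL) {
  stopifnot(inherits(data, "pu_dataset"))
  df <- data.frame(sample_id = rownames(data$features),
                   data$features,
                   pu_label = data$pu_labels,
                   check.names = FALSE)
  if (!is.null(data$truth_labels)) df$truth_label <- data$truth_labels
  write.csv(df, path, row.names = FALSE)
  if (!is.null(config)) {
    sidecar <- sub("\\.[^.]+$", ".yaml", path)
    yaml::write_yaml(c(unclass(config), list(n_kp = n_kp)), sidecar)
  }
  invisible(path)
}
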