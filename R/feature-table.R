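#' Canonical feature names
#'
#' The 75 summary-feature identifiers in fixed canonical order: 15 frame-level
#' descriptor methods crossed with 5 pooled statistics (min, max, mean, sd,
#' skew). Every feature table produced or consumed by this package uses this
#' column order.
#'
#' @return Character vector of length 75, names of the form `<method>_<stat>`.
#' @export
#' @examples
#' head(feature_names())
feature_names <- function() {
  as.vector(t(outer(descriptor_ids(), summary_stat_ids(),
                    function(m, s) paste(m, s, sep = "_"))))
}

#' Identifiers of the 15 frame-level descriptor methods, in canonical order.
#' @return Character vector of length 15.
#' @export
descriptor_ids <- function() {
  c("chroma_stft", "chroma_cqt", "chroma_cens", "chroma_vqt", "mfcc",
    "melspec", "rms", "spec_centroid", "spec_bandwidth", "spec_contrast",
    "spec_flatness", "spec_rolloff", "poly", "tonnetz", "zcr")
}

#' Identifiers of the 5 pooled summary statistics, in canonical order.
#' @return Character vector of length 5.
#' @export
summary_stat_ids <- function() c("min", "max", "mean", "sd", "skew")

#' Construct a feature table
#'
#' The central data container: an N x D numeric feature matrix with one row
#' per recording, a class label per row, and a class-scheme tag describing
#' the labelling in force (e.g. binary healthy/diseased or the three-class
#' healthy/chronic/non-chronic scheme).
#'
#' @param features numeric matrix (rows = recordings, columns = features)
#'   with column names.
#' @param labels factor (or coercible) of length `nrow(features)`.
#' @param recording_id character vector of row identifiers; defaults to
#'   `rec_1 ... rec_N`.
#' @param scheme free-text tag for the labelling scheme (e.g. `"case1"`).
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(features, labels,
                          recording_id = NULL, scheme = "unspecified") {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  }
  labels <- as.factor(labels)
  if (length(labels) != nrow(features)) {
    stop("labels: length ", length(labels), " does not match ",
         nrow(features), " rows of features")
  }
  if (anyNA(features) || any(!is.finite(features))) {
    stop("features: non-finite values are not allowed")
  }
  if (is.null(recording_id)) {
    recording_id <- paste0("rec_", seq_len(nrow(features)))
  }
  structure(
    list(features = features, labels = labels,
         recording_id = as.character(recording_id), scheme = scheme),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$features), " recordings x ",
      ncol(x$features), " features; scheme = ", x$scheme, "\n", sep = "")
  print(table(x$labels))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$features)

#' Subset the rows of a feature table
#' @param table a `feature_table`.
#' @param idx integer or logical row index.
#' @return A `feature_table` with the selected rows.
#' @export
ft_rows <- function(table, idx) {
  feature_table(table$features[idx, , drop = FALSE],
                droplevels(table$labels[idx]),
                table$recording_id[idx], table$scheme)
}

#' Write a feature table to CSV
#'
#' Layout: `recording_id`, `label`, then the feature columns in table order.
#' Full double precision (17 significant digits) so a write/read round trip
#' is bit-comparable.
#'
#' @param table a `feature_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(recording_id = table$recording_id,
                   label = as.character(table$labels),
                   table$features, check.names = FALSE,
                   stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = ","), con)
  num <- vapply(seq_len(nrow(df)), function(i) {
    paste(c(df$recording_id[i], df$label[i],
            formatC(table$features[i, ], format = "g", digits = 17)),
          collapse = ",")
  }, character(1))
  writeLines(num, con)
  invisible(path)
}

#' Read a feature table from CSV
#' @param path file written by [write_feature_table()].
#' @param scheme class-scheme tag to attach.
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path, scheme = "unspecified") {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("recording_id", "label") %in% colnames(df))) {
    stop("feature-table CSV must contain recording_id and label columns")
  }
  feat_cols <- setdiff(colnames(df), c("recording_id", "label"))
  feature_table(as.matrix(df[, feat_cols, drop = FALSE]),
                df$label, df$recording_id, scheme)
}
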