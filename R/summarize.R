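#' Pool a descriptor matrix into five summary statistics
#'
#' Statistics are pooled over ALL entries of the matrix — coefficients and
#' frames jointly — yielding exactly five values per descriptor method:
#' minimum, maximum, mean, population standard deviation (ddof = 0), and
#' skewness (bias-uncorrected Fisher-Pearson moment coefficient g1).
#' Zero-variance input has skewness 0 by convention.
#'
#' @param matrix a `spectral_feature_matrix` (from
#'   [extract_frame_features()]) or a bare numeric matrix/vector.
#' @return Named numeric vector `c(min, max, mean, sd, skew)`.
#' @export
#' @examples
#' summarize_features(matrix(c(1, 2, 3), 1))
summarize_features <- function(matrix) {
  v <- if (inherits(matrix, "spectral_feature_matrix")) {
    as.numeric(matrix$values)
  } else {
    as.numeric(matrix)
  }
  if (length(v) == 0) stop("cannot summarize an empty matrix")
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  skew <- if (s > 0) mean((v - m)^3) / s^3 else 0
  c(min = min(v), max = max(v), mean = m, sd = s, skew = skew)
}

#' Extract the full 75-value summary feature vector for one clip
#'
#' Runs all 15 descriptor methods over a shared spectrogram and pools each
#' with the five summary statistics, in canonical [feature_names()] order.
#'
#' @param clip an [audio_clip()].
#' @return Named numeric vector of length 75.
#' @export
extract_features <- function(clip) {
  stopifnot(inherits(clip, "audio_clip"))
  ctx <- analysis_context(clip)
  out <- unlist(lapply(descriptor_ids(), function(id) {
    summarize_features(.descriptor_registry[[id]](ctx))
  }), use.names = FALSE)
  names(out) <- feature_names()
  out
}

#' Build a feature table from labelled audio clips
#'
#' One row per clip with the 75 canonical summary features. Clips whose
#' summary contains any non-finite value are dropped with a message naming
#' the clip.
#'
#' @param clips list of [audio_clip()] objects.
#' @param labels class labels, one per clip.
#' @param scheme class-scheme tag for the resulting table.
#' @return A [feature_table()] with up to `length(clips)` rows.
#' @export
build_feature_table <- function(clips, labels, scheme = "audio") {
  if (length(clips) == 0) stop("no clips supplied")
  if (length(labels) != length(clips)) {
    stop("labels: need one label per clip")
  }
  rows <- lapply(clips, function(clip) {
    tryCatch(extract_features(clip), error = function(e) {
      message("dropping clip '", clip$recording_id, "': ",
              conditionMessage(e))
      NULL
    })
  })
  ok <- !vapply(rows, is.null, logical(1))
  finite <- ok
  finite[ok] <- vapply(rows[ok], function(r) all(is.finite(r)), logical(1))
  for (i in which(ok & !finite)) {
    message("dropping clip '", clips[[i]]$recording_id,
            "': non-finite summary value")
  }
  keep <- ok & finite
  if (!any(keep)) stop("every clip was rejected")
  feature_table(do.call(rbind, rows[keep]),
                factor(as.character(labels)[keep]),
                vapply(clips[keep], `[[`, character(1), "recording_id"),
                scheme)
}

#' Settings sidecar describing the extraction configuration
#'
#' Writes a JSON record of the effective extractor settings (frame length,
#' hop, descriptor list, statistic list) next to a feature-table CSV so a
#' run can be reproduced.
#'
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_extractor_settings <- function(path) {
  jsonlite::write_json(
    list(n_fft = .default_n_fft, hop = .default_hop, window = "hann",
         descriptors = descriptor_ids(), statistics = summary_stat_ids(),
         sd_convention = "population (ddof = 0)",
         skew_convention = "g1, 0 for zero variance"),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
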