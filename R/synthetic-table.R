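#' Specification for a synthetic feature table
#'
#' Describes a Gaussian emulation of an audio-derived summary-feature table
#' with planted signal. A configurable number of "informative" columns get
#' class-specific means separated by `effect_size` within-class standard
#' deviations; the remaining columns are pure noise, identically distributed
#' across classes. Defaults reproduce the binary class imbalance of the
#' respiratory-sound study this package emulates (35 healthy vs 885 diseased
#' recordings, 75 features).
#'
#' @param class_sizes positive integer vector, one entry per class. Defaults
#'   to `c(healthy = 35, diseased = 885)`. The three-class scheme of the
#'   study is `c(healthy = 35, chronic = 810, non_chronic = 75)`.
#' @param n_features number of feature columns (default 75).
#' @param n_informative number of columns carrying class signal, in
#'   `[0, n_features]` (default 10).
#' @param effect_size class-mean separation in units of the within-class
#'   standard deviation (default 1.5); successive classes are offset by
#'   `effect_size * noise_sd` on each informative column.
#' @param noise_sd within-class standard deviation of every column
#'   (default 1).
#' @param seed integer seed; regeneration with the same spec is bit-identical.
#' @return An object of class `synthetic_table_spec`.
#' @export
synthetic_table_spec <- function(class_sizes = c(healthy = 35, diseased = 885),
                                 n_features = 75,
                                 n_informative = 10,
                                 effect_size = 1.5,
                                 noise_sd = 1,
                                 seed = 1L) {
  if (length(class_sizes) < 1 || any(class_sizes < 1) ||
      any(class_sizes != round(class_sizes))) {
    stop("class_sizes: must be positive integers, one per class")
  }
  if (n_features < 1 || n_features != round(n_features)) {
    stop("n_features: must be a positive integer")
  }
  if (n_informative < 0 || n_informative > n_features) {
    stop("n_informative: must lie in [0, n_features]")
  }
  if (effect_size < 0) stop("effect_size: must be non-negative")
  if (noise_sd <= 0) stop("noise_sd: must be positive")
  if (is.null(names(class_sizes))) {
    names(class_sizes) <- paste0("class", seq_along(class_sizes))
  }
  structure(
    list(class_sizes = class_sizes, n_features = as.integer(n_features),
         n_informative = as.integer(n_informative),
         effect_size = effect_size, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "synthetic_table_spec"
  )
}

#' Generate a synthetic feature table with known ground truth
#'
#' Informative columns are drawn from class-specific Gaussians whose means
#' step by `effect_size * noise_sd` per class; the other columns are
#' N(0, noise_sd^2) regardless of class. Rows are emitted class by class so
#' label counts equal `spec$class_sizes` exactly. Column names follow the
#' canonical 75-name glossary when `n_features == 75`, otherwise `f1..fD`.
#'
#' @param spec a [synthetic_table_spec()].
#' @return A list with elements `table` (a [feature_table()]) and
#'   `ground_truth` (list with `informative_indices` — which columns carry
#'   signal — and `class_means`, the classes x informative matrix of true
#'   means).
#' @export
#' @examples
#' out <- generate_feature_table(synthetic_table_spec(
#'   class_sizes = c(30, 30), n_features = 10, n_informative = 3,
#'   effect_size = 2, seed = 7))
#' table(out$table$labels)
#' out$ground_truth$informative_indices
generate_feature_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_table_spec"))
  n <- sum(spec$class_sizes)
  d <- spec$n_features
  k <- length(spec$class_sizes)
  withr::with_seed(spec$seed, {
    informative <- if (spec$n_informative > 0) {
      sort(sample.int(d, spec$n_informative))
    } else integer(0)
    x <- matrix(rnorm(n * d, sd = spec$noise_sd), nrow = n, ncol = d)
    class_means <- outer(seq_len(k) - 1L,
                         rep(spec$effect_size * spec$noise_sd,
                             spec$n_informative))
    labels <- rep(names(spec$class_sizes), times = spec$class_sizes)
    if (spec$n_informative > 0) {
      row_class <- rep(seq_len(k), times = spec$class_sizes)
      x[, informative] <- x[, informative, drop = FALSE] +
        class_means[row_class, , drop = FALSE]
    }
  })
  colnames(x) <- if (d == 75) feature_names() else paste0("f", seq_len(d))
  rownames(class_means) <- names(spec$class_sizes)
  list(
    table = feature_table(x, factor(labels, levels = names(spec$class_sizes)),
                          scheme = if (k == 2) "case1" else
                                   if (k == 3) "case2" else "synthetic"),
    ground_truth = list(informative_indices = informative,
                        class_means = class_means)
  )
}
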