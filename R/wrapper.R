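#' Train/test split specification
#'
#' The evaluation protocol keeps a single held-out fraction (default 20%,
#' seed 42) that is reused both inside the wrapper objective and for final
#' reporting — deliberately mirroring the single-fixed-split protocol of the
#' study this package emulates, which leaks selection information into the
#' reported metrics. Stratification is on by default so a small minority
#' class (35 of 920 recordings) cannot vanish from the test set.
#'
#' @param test_fraction fraction held out, in (0, 1) (default 0.2).
#' @param seed split seed (default 42).
#' @param stratified preserve per-class proportions (default TRUE).
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(test_fraction = 0.2, seed = 42L, stratified = TRUE) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction: must lie strictly between 0 and 1")
  }
  structure(list(test_fraction = test_fraction, seed = as.integer(seed),
                 stratified = stratified),
            class = "split_spec")
}

#' Split a feature table into train and test index sets
#'
#' Stratified mode draws `round(test_fraction * n_c)` test rows per class
#' (at least 1, at most `n_c - 1`), so per-class test proportions are within
#' one sample of `test_fraction`. Non-stratified mode samples the pooled
#' rows. Deterministic for a fixed seed.
#'
#' @param table a [feature_table()].
#' @param spec a [split_spec()].
#' @return List with integer vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
stratified_split <- function(table, spec = split_spec()) {
  stopifnot(inherits(table, "feature_table"), inherits(spec, "split_spec"))
  n <- nrow(table$features)
  withr::with_seed(spec$seed, {
    if (spec$stratified) {
      counts <- table(table$labels)
      if (any(counts < 2)) {
        stop("class '", names(counts)[which(counts < 2)[1]],
             "' has fewer than 2 members; use stratified = FALSE")
      }
      test <- integer(0)
      for (cl in levels(table$labels)) {
        rows <- which(table$labels == cl)
        n_test <- min(max(1L, round(spec$test_fraction * length(rows))),
                      length(rows) - 1L)
        test <- c(test, sort(sample(rows, n_test)))
      }
      test <- sort(test)
    } else {
      n_test <- min(max(1L, round(spec$test_fraction * n)), n - 1L)
      test <- sort(sample.int(n, n_test))
    }
  })
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Fitness weighting between MCC and subset size
#' @param alpha weight on the MCC term, in \[0, 1\] (default 0.99); the
#'   complementary weight multiplies `1 - n_selected / D`.
#' @return An object of class `fitness_config`.
#' @export
fitness_config <- function(alpha = 0.99) {
  if (alpha < 0 || alpha > 1) stop("alpha: must lie in [0, 1]")
  structure(list(alpha = alpha), class = "fitness_config")
}

#' Ensure a mask selects at least one feature
#'
#' An all-zero mask is unevaluable; one uniformly chosen bit is set (using
#' R's current RNG stream). Non-empty masks pass through unchanged.
#'
#' @param mask integer 0/1 vector.
#' @return Integer 0/1 vector with at least one bit set.
#' @export
repair_mask <- function(mask) {
  if (sum(mask) == 0L) mask[sample.int(length(mask), 1)] <- 1L
  mask
}

#' Evaluate a feature mask with the wrapper objective
#'
#' Fits KNN on the training partition restricted to the masked columns,
#' predicts the held-out partition, and combines test MCC with a subset-size
#' penalty:
#' \deqn{fitness = \alpha \cdot MCC + (1-\alpha)(1 - n_{sel}/D)}
#'
#' @param mask integer 0/1 vector over the table's columns, already repaired
#'   (at least one bit set).
#' @param table a [feature_table()].
#' @param split index list from [stratified_split()].
#' @param fit_cfg a [fitness_config()].
#' @param k KNN neighbourhood size (default 5).
#' @param standardize z-score on training statistics (default FALSE).
#' @return List: `fitness`, and `evaluation` with `mcc`, `accuracy`,
#'   `balanced_accuracy`, `f1_macro`, `n_selected`, `fitness`.
#' @export
evaluate_mask <- function(mask, table, split, fit_cfg = fitness_config(),
                          k = 5L, standardize = FALSE) {
  if (sum(mask) == 0) stop("mask selects no features; repair it first")
  x <- table$features
  y_train <- table$labels[split$train]
  y_test <- table$labels[split$test]
  pred <- knn_predict(x[split$train, , drop = FALSE],
                      x[split$test, , drop = FALSE],
                      y_train, mask, k = k, standardize = standardize)
  m <- mcc(y_test, pred)
  ms <- metric_suite(y_test, pred)
  n_sel <- sum(mask)
  fit <- fit_cfg$alpha * m +
    (1 - fit_cfg$alpha) * (1 - n_sel / ncol(x))
  list(fitness = fit,
       evaluation = list(mcc = m, accuracy = ms$accuracy,
                         balanced_accuracy = ms$balanced_accuracy,
                         f1_macro = ms$f1_macro,
                         n_selected = n_sel, fitness = fit))
}

#' Build the continuous feature-selection objective for an optimizer
#'
#' Wraps [binarize()], [repair_mask()] and [evaluate_mask()] into the
#' function that [run_optimizer()] maximizes. The transfer function is
#' applied to the candidate's *move* (the step that produced it; the
#' position itself for the initial population), the convention of the
#' binary-metaheuristic literature: as the population converges, steps
#' shrink toward 0, so V-shaped functions — which vanish at 0 — switch bits
#' off and masks become sparse, while S-shaped functions keep each bit with
#' probability near 0.5. Evaluations are memoized on the mask bit-string, so
#' re-visiting a mask costs nothing (the stochastic binarization still
#' consumes RNG draws, keeping trajectories reproducible).
#'
#' @param table a [feature_table()].
#' @param split index list from [stratified_split()].
#' @param tf_id transfer function id, `"S1" ... "V4"`.
#' @param fit_cfg a [fitness_config()].
#' @param k KNN neighbourhood size.
#' @param v_rule binarization rule, `"set"` or `"flip"` (see [binarize()]).
#' @param standardize z-score features on training statistics.
#' @return Function of a position vector returning
#'   `list(fitness, diagnostics)`; diagnostics carry the mask and metrics.
#' @export
make_fs_objective <- function(table, split, tf_id,
                              fit_cfg = fitness_config(), k = 5L,
                              v_rule = "set", standardize = FALSE) {
  cache <- new.env(parent = emptyenv())
  force(tf_id)
  function(position, step = position) {
    mask <- repair_mask(binarize(step, tf_id, v_rule = v_rule,
                                 current = as.integer(position > 0)))
    key <- paste(mask, collapse = "")
    hit <- cache[[key]]
    if (is.null(hit)) {
      hit <- evaluate_mask(mask, table, split, fit_cfg, k = k,
                           standardize = standardize)
      cache[[key]] <- hit
    }
    list(fitness = hit$fitness,
         diagnostics = c(list(mask = mask), hit$evaluation))
  }
}

#' Run one feature-selection cell (algorithm x transfer function)
#'
#' @param table a [feature_table()].
#' @param algorithm optimizer name (see [optimizer_config()]).
#' @param tf_id transfer function id.
#' @param opt_cfg an [optimizer_config()]; its `algorithm` and `seed` fields
#'   are overridden by `algorithm` and `seed` when given.
#' @param split_cfg a [split_spec()].
#' @param fit_cfg a [fitness_config()].
#' @param seed optional optimizer seed override.
#' @param k KNN neighbourhood size.
#' @param v_rule binarization rule.
#' @return List: `algorithm`, `transfer_function`, `seed`, `best` (mask,
#'   metrics, position), `curve`, `n_evaluations`, `split`.
#' @export
select_features <- function(table, algorithm, tf_id,
                            opt_cfg = optimizer_config(algorithm),
                            split_cfg = split_spec(),
                            fit_cfg = fitness_config(),
                            seed = NULL, k = 5L, v_rule = "set") {
  if (!is.null(seed)) opt_cfg$seed <- as.integer(seed)
  opt_cfg$algorithm <- algorithm
  split <- stratified_split(table, split_cfg)
  objective <- make_fs_objective(table, split, tf_id, fit_cfg, k = k,
                                 v_rule = v_rule)
  res <- run_optimizer(objective, ncol(table$features), opt_cfg)
  list(algorithm = algorithm, transfer_function = tf_id,
       seed = opt_cfg$seed, best = res$best, curve = res$curve,
       n_evaluations = res$n_evaluations, split = split)
}
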