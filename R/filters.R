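#' Score features with a classical filter selector
#'
#' Closed-form per-feature relevance scores (higher = more relevant),
#' computed on the training partition only:
#' * `VAR` — population variance.
#' * `MAD` — mean absolute difference, `mean(|x - mean(x)|)`.
#' * `DR` — dispersion ratio, arithmetic mean / geometric mean; features with
#'   any value `<= 0` are first shifted by `1 - min(x)` so the geometric mean
#'   is defined. Scale-invariant for positive features; 1 for constants.
#' * `SPEARMAN` — absolute Spearman rank correlation between the feature and
#'   an integer-coded label; constant features score 0.
#'
#' @param table a [feature_table()] (typically the training rows).
#' @param method one of `"VAR"`, `"MAD"`, `"DR"`, `"SPEARMAN"`.
#' @return List of class `feature_score`: `method`, `scores` (length-D named
#'   numeric).
#' @export
score_features <- function(table, method = c("VAR", "MAD", "DR", "SPEARMAN")) {
  method <- match.arg(method)
  x <- table$features
  if (nrow(x) < 2) stop("need at least 2 training rows")
  n <- nrow(x)
  scores <- switch(method,
    VAR = colMeans(x^2) - colMeans(x)^2,
    MAD = colMeans(abs(sweep(x, 2, colMeans(x)))),
    DR = apply(x, 2, function(v) {
      if (min(v) <= 0) v <- v + 1 - min(v)
      mean(v) / exp(mean(log(v)))
    }),
    SPEARMAN = {
      y <- as.integer(table$labels)
      apply(x, 2, function(v) {
        if (sd(v) == 0 || sd(y) == 0) return(0)
        abs(cor(v, y, method = "spearman"))
      })
    })
  structure(list(method = method, scores = scores), class = "feature_score")
}

#' Sweep the number of top-ranked features for the highest test MCC
#'
#' For each `k` in `k_range`, selects the `k` highest-scoring features
#' (score ties broken by column index, so equal scores keep the earlier
#' feature), evaluates test MCC with KNN on the fixed split, and returns the
#' `k` that maximizes MCC (smallest such `k` on ties).
#'
#' @param table a [feature_table()].
#' @param method filter method passed to [score_features()].
#' @param split index list from [stratified_split()].
#' @param k_range integer vector of candidate subset sizes within
#'   `[1, ncol]`.
#' @param k_nn KNN neighbourhood size (default 5).
#' @return List: `method`, `best_k`, `best_mcc`, `selected` (column indices
#'   at `best_k`), `evaluation` (full metric list at `best_k`), and `sweep`
#'   (data.frame of k vs mcc).
#' @export
sweep_k <- function(table, method, split, k_range = seq_len(ncol(table$features)),
                    k_nn = 5L) {
  d <- ncol(table$features)
  if (length(k_range) == 0) stop("empty k range")
  if (any(k_range < 1 | k_range > d)) stop("k range outside [1, D]")
  fs <- score_features(ft_rows(table, split$train), method)
  ranking <- order(fs$scores, decreasing = TRUE)   # stable: index breaks ties
  k_range <- sort(unique(as.integer(k_range)))
  mccs <- numeric(length(k_range))
  evals <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    mask <- integer(d)
    mask[ranking[seq_len(k_range[i])]] <- 1L
    ev <- evaluate_mask(mask, table, split, fitness_config(1), k = k_nn)
    mccs[i] <- ev$evaluation$mcc
    evals[[i]] <- ev$evaluation
  }
  best <- which.max(mccs)   # first max = smallest k on ties
  list(method = method,
       best_k = k_range[best],
       best_mcc = mccs[best],
       selected = sort(ranking[seq_len(k_range[best])]),
       evaluation = evals[[best]],
       sweep = data.frame(k = k_range, mcc = mccs))
}
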