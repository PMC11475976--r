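#' K-nearest-neighbour prediction on a masked feature subset
#'
#' Majority vote over the `k` nearest training rows by Euclidean distance
#' restricted to the columns selected by `mask`. Tie handling is
#' deterministic: distance ties are broken by training-row order (stable
#' sort), and vote ties by the class of the nearest single neighbour among
#' the tied classes. Optionally z-scores features using means/sds fit on the
#' training rows.
#'
#' @param train_x,test_x numeric matrices with identical column layout.
#' @param train_y labels for `train_x` rows.
#' @param mask integer 0/1 vector over columns; must select at least one.
#' @param k neighbourhood size (default 5); must not exceed `nrow(train_x)`.
#' @param standardize z-score columns on training statistics (default off;
#'   constant columns are left unscaled).
#' @return Factor of predicted labels, one per test row.
#' @export
knn_predict <- function(train_x, test_x, train_y, mask = NULL, k = 5L,
                        standardize = FALSE) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  if (nrow(train_x) == 0) stop("empty training set")
  if (k > nrow(train_x)) {
    stop("k = ", k, " exceeds the ", nrow(train_x), " training rows")
  }
  if (is.null(mask)) mask <- rep(1L, ncol(train_x))
  sel <- which(mask == 1L)
  if (length(sel) == 0) stop("mask selects no features")
  tr <- train_x[, sel, drop = FALSE]
  te <- test_x[, sel, drop = FALSE]
  if (standardize) {
    mu <- colMeans(tr)
    sdev <- apply(tr, 2, sd)
    sdev[sdev == 0] <- 1
    tr <- sweep(sweep(tr, 2, mu), 2, sdev, "/")
    te <- sweep(sweep(te, 2, mu), 2, sdev, "/")
  }
  train_y <- as.factor(train_y)
  n_class <- nlevels(train_y)
  y_int <- as.integer(train_y)
  # squared Euclidean distances, test rows x train rows
  d2 <- outer(rowSums(te^2), rowSums(tr^2), `+`) - 2 * tcrossprod(te, tr)
  # k nearest by repeated argmin; ties.method = "first" makes distance ties
  # resolve to the earlier training row
  n_test <- nrow(te)
  nn_class <- matrix(0L, n_test, k)      # class of j-th nearest neighbour
  for (j in seq_len(k)) {
    idx <- max.col(-d2, ties.method = "first")
    nn_class[, j] <- y_int[idx]
    d2[cbind(seq_len(n_test), idx)] <- Inf
  }
  counts <- vapply(seq_len(n_class),
                   function(cl) rowSums(nn_class == cl),
                   numeric(n_test))
  counts <- matrix(counts, nrow = n_test)
  top_count <- counts[cbind(seq_len(n_test),
                            max.col(counts, ties.method = "first"))]
  # majority vote; vote ties go to the class of the nearest neighbour that
  # belongs to one of the tied classes
  pred <- integer(n_test)
  undecided <- rep(TRUE, n_test)
  for (j in seq_len(k)) {
    cl <- nn_class[, j]
    hit <- undecided & counts[cbind(seq_len(n_test), cl)] == top_count
    pred[hit] <- cl[hit]
    undecided <- undecided & !hit
    if (!any(undecided)) break
  }
  factor(levels(train_y)[pred], levels = levels(train_y))
}
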