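make_table <- function(n_a = 50, n_b = 50, d = 6, seed = 3) {
  small_table(n_per_class = n_a, d = d, n_informative = 2, effect = 2,
              seed = seed)$table
}

test_that("stratified splits are exhaustive, proportional and seeded", {
  tab <- make_table()
  sp <- stratified_split(tab, split_spec(0.2, seed = 42))
  expect_length(sp$test, 20)
  expect_length(sp$train, 80)
  expect_setequal(c(sp$train, sp$test), 1:100)
  sp2 <- stratified_split(tab, split_spec(0.2, seed = 42))
  expect_identical(sp, sp2)
})

test_that("the study-sized imbalanced split keeps 7 +/- 1 minority test rows", {
  out <- generate_feature_table(synthetic_table_spec(seed = 2))
  sp <- stratified_split(out$table, split_spec())
  healthy_test <- sum(out$table$labels[sp$test] == "healthy")
  expect_lte(abs(healthy_test - 0.2 * 35), 1)
  # every class present in both partitions
  expect_setequal(unique(as.character(out$table$labels[sp$train])),
                  levels(out$table$labels))
  expect_setequal(unique(as.character(out$table$labels[sp$test])),
                  levels(out$table$labels))
})

test_that("a singleton class fails stratification with advice", {
  tab <- feature_table(matrix(rnorm(10), 5), c("a", "a", "a", "a", "b"))
  expect_error(stratified_split(tab, split_spec()), "stratified = FALSE")
  expect_no_error(stratified_split(tab, split_spec(stratified = FALSE)))
})

test_that("KNN honors exact matches, separable blobs and contracts", {
  tab <- make_table()
  x <- tab$features
  # k = 1 with a test point equal to a unique training point
  pred <- knn_predict(x, x[7, , drop = FALSE], tab$labels, k = 1)
  expect_equal(as.character(pred), as.character(tab$labels[7]))
  # two blobs separated far beyond their spread: perfect classification
  blob <- small_table(n_per_class = 30, d = 4, n_informative = 4,
                      effect = 10, seed = 1)$table
  sp <- stratified_split(blob, split_spec())
  pred <- knn_predict(blob$features[sp$train, ], blob$features[sp$test, ],
                      blob$labels[sp$train], k = 5)
  expect_equal(mean(pred == blob$labels[sp$test]), 1)
  expect_error(knn_predict(x, x, tab$labels, mask = rep(0L, 6)), "mask")
  expect_error(knn_predict(x[1:3, ], x, tab$labels[1:3], k = 5), "exceeds")
})

test_that("MCC matches its closed forms and conventions", {
  expect_equal(mcc(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(mcc(c(1, 0, 1, 0), c(1, 1, 1, 1)), 0)  # constant predictor
  y_true <- rep(c("pos", "neg"), c(50, 50))
  y_pred <- rep(c("pos", "neg", "pos", "neg"), c(45, 5, 5, 45))
  expect_equal(mcc(y_true, y_pred), 0.8)               # TP45 FN5 FP5 TN45
  y3 <- rep(c("a", "b", "c"), each = 10)
  expect_equal(mcc(y3, y3), 1)                         # perfect 3-class
  expect_error(mcc(1:3, 1:4), "length")
})

test_that("binary MCC equals the Pearson correlation of 0/1 vectors", {
  withr::with_seed(99, {
    for (i in 1:100) {
      n <- sample(10:60, 1)
      yt <- sample(0:1, n, replace = TRUE)
      yp <- sample(0:1, n, replace = TRUE)
      expected <- suppressWarnings(cor(yt, yp))
      if (is.na(expected)) expected <- 0
      expect_equal(mcc(yt, yp), expected, tolerance = 1e-12)
    }
  })
})

test_that("MCC is invariant under joint relabeling", {
  withr::with_seed(11, {
    yt <- sample(c("x", "y", "z"), 60, replace = TRUE)
    yp <- sample(c("x", "y", "z"), 60, replace = TRUE)
    relabel <- c(x = "beta", y = "gamma", z = "alpha")
    expect_equal(mcc(yt, yp), mcc(relabel[yt], relabel[yp]))
  })
})

test_that("metric suite matches hand computations", {
  perfect <- metric_suite(c(1, 2, 1), c(1, 2, 1))
  expect_equal(unlist(perfect), c(accuracy = 1, balanced_accuracy = 1,
                                  f1_macro = 1))
  yt <- rep(c("A", "B"), c(90, 10))
  ms <- metric_suite(yt, rep("A", 100))
  expect_equal(ms$accuracy, 0.9)
  expect_equal(ms$balanced_accuracy, 0.5)
  swapped <- metric_suite(c("A", "A", "B", "B"), c("B", "B", "A", "A"))
  expect_equal(swapped$balanced_accuracy, 0)
})

test_that("fitness combines MCC and subset size as documented", {
  blob <- small_table(n_per_class = 30, d = 10, n_informative = 10,
                      effect = 10, seed = 21)$table   # MCC = 1 territory
  sp <- stratified_split(blob, split_spec())
  full <- evaluate_mask(rep(1L, 10), blob, sp, fitness_config(0.99))
  expect_equal(full$evaluation$mcc, 1)
  expect_equal(full$fitness, 0.99)                    # alpha when all selected
  one <- evaluate_mask(c(1L, rep(0L, 9)), blob, sp, fitness_config(0.99))
  expect_equal(one$fitness,
               0.99 * one$evaluation$mcc + 0.01 * (1 - 1 / 10))
  # alpha = 1 reduces fitness to MCC for any mask
  m <- c(1L, 1L, 0L, 1L, 0L, 0L, 1L, 0L, 0L, 0L)
  ev <- evaluate_mask(m, blob, sp, fitness_config(1))
  expect_equal(ev$fitness, ev$evaluation$mcc)
  # more features at equal MCC means strictly lower fitness when alpha < 1
  fit_k <- function(k) 0.99 * 1 + 0.01 * (1 - k / 10)
  expect_true(all(diff(vapply(1:10, fit_k, numeric(1))) < 0))
})

test_that("mask repair sets exactly one uniform bit on empty masks", {
  expect_identical(repair_mask(c(0L, 1L, 0L)), c(0L, 1L, 0L))
  withr::with_seed(5, {
    repaired <- repair_mask(rep(0L, 10))
    expect_equal(sum(repaired), 1)
    counts <- integer(10)
    for (i in 1:10000) {
      counts <- counts + repair_mask(rep(0L, 10))
    }
    expect_true(all(abs(counts / 10000 - 0.1) <
                      3 * sqrt(0.1 * 0.9 / 10000)))
  })
})

test_that("diagnosis mapping follows the two case schemes and rejects strays", {
  expect_equal(as.character(map_diagnosis_to_case("COPD", 2)), "chronic")
  expect_equal(as.character(map_diagnosis_to_case("Healthy", 1)), "healthy")
  expect_equal(as.character(map_diagnosis_to_case("Healthy", 2)), "healthy")
  expect_equal(as.character(map_diagnosis_to_case("URTI", 1)), "diseased")
  expect_equal(as.character(map_diagnosis_to_case(
    c("Pneumonia", "Bronchiolitis", "LRTI", "URTI"), 2)),
    rep("non_chronic", 4))
  expect_equal(as.character(map_diagnosis_to_case(
    c("Asthma", "Bronchiectasis"), 2)), rep("chronic", 2))
  expect_error(map_diagnosis_to_case("Cystic Fibrosis", 2),
               "Cystic Fibrosis")
  expect_error(map_diagnosis_to_case("COPD", 3), "case")
})

test_that("the memoized objective matches direct evaluation and repairs masks", {
  tab <- make_table()
  sp <- stratified_split(tab, split_spec())
  obj <- make_fs_objective(tab, sp, "S2")
  withr::with_seed(8, {
    res <- obj(rep(4, 6))       # S2(4) ~ 0.982: almost surely all selected
  })
  direct <- evaluate_mask(res$diagnostics$mask, tab, sp)
  expect_equal(res$fitness, direct$fitness)
  withr::with_seed(9, {
    res0 <- obj(rep(-50, 6))    # S2(-50) = 0: all-zero mask, then repaired
  })
  expect_equal(res0$diagnostics$n_selected, 1)
})
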