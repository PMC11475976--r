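test_that("generated tables honor class sizes, naming and reproducibility", {
  spec <- synthetic_table_spec()
  out <- generate_feature_table(spec)
  expect_equal(as.vector(table(out$table$labels)), c(35, 885))
  expect_equal(levels(out$table$labels), c("healthy", "diseased"))
  expect_equal(dim(out$table$features), c(920, 75))
  expect_identical(colnames(out$table$features), feature_names())

  spec3 <- synthetic_table_spec(
    class_sizes = c(healthy = 35, chronic = 810, non_chronic = 75))
  out3 <- generate_feature_table(spec3)
  expect_equal(as.vector(table(out3$table$labels)), c(35, 810, 75))
  expect_identical(out3$table$scheme, "case2")

  again <- generate_feature_table(spec)
  expect_identical(out$table$features, again$table$features)
  expect_identical(out$ground_truth, again$ground_truth)
})

test_that("ground truth indices are unique, in range, of the stated size", {
  for (ni in c(0, 1, 5, 75)) {
    out <- generate_feature_table(synthetic_table_spec(
      class_sizes = c(10, 10), n_informative = ni, seed = ni + 1))
    idx <- out$ground_truth$informative_indices
    expect_length(idx, ni)
    expect_false(anyDuplicated(idx) > 0)
    if (ni > 0) expect_true(all(idx >= 1 & idx <= 75))
  }
})

test_that("invalid table specs name the violated field", {
  expect_error(synthetic_table_spec(class_sizes = c(0, 10)), "class_sizes")
  expect_error(synthetic_table_spec(n_features = 0), "n_features")
  expect_error(synthetic_table_spec(n_informative = 80), "n_informative")
  expect_error(synthetic_table_spec(effect_size = -1), "effect_size")
  expect_error(synthetic_table_spec(noise_sd = 0), "noise_sd")
})

test_that("non-informative columns are class-independent; informative ones shift", {
  out <- generate_feature_table(synthetic_table_spec(
    class_sizes = c(400, 400), n_features = 10, n_informative = 3,
    effect_size = 2, seed = 5))
  tab <- out$table
  idx <- out$ground_truth$informative_indices
  noise_col <- setdiff(seq_len(10), idx)[1]
  a <- tab$features[tab$labels == levels(tab$labels)[1], noise_col]
  b <- tab$features[tab$labels == levels(tab$labels)[2], noise_col]
  expect_gt(suppressWarnings(ks.test(a, b)$p.value), 0.01)
  shift <- mean(tab$features[tab$labels == levels(tab$labels)[2], idx[1]]) -
    mean(tab$features[tab$labels == levels(tab$labels)[1], idx[1]])
  expect_equal(shift, 2, tolerance = 0.15)
})

test_that("no planted signal means no recoverable signal (MCC near 0)", {
  out <- generate_feature_table(synthetic_table_spec(
    class_sizes = c(100, 100), n_features = 20, n_informative = 0, seed = 9))
  split <- stratified_split(out$table, split_spec())
  ev <- evaluate_mask(rep(1L, 20), out$table, split, fitness_config(1))
  expect_lt(abs(ev$evaluation$mcc), 0.35)
})

test_that("planted signal is recoverable: KNN on the 5 true columns has MCC > 0.9", {
  out <- generate_feature_table(synthetic_table_spec(
    class_sizes = c(100, 100), n_features = 75, n_informative = 5,
    effect_size = 3, seed = 13))
  split <- stratified_split(out$table, split_spec())
  mask <- integer(75)
  mask[out$ground_truth$informative_indices] <- 1L
  ev <- evaluate_mask(mask, out$table, split, fitness_config(1))
  expect_gt(ev$evaluation$mcc, 0.9)
})

test_that("synthetic audio datasets are counted, bounded and reproducible", {
  spec <- synthetic_audio_spec(n_clips_per_class = 3, duration_s = 0.25,
                               sample_rate = 22050, seed = 4)
  ds <- generate_audio_dataset(spec)
  expect_length(ds$clips, 6)
  expect_equal(as.vector(table(ds$labels)), c(3, 3))
  for (clip in ds$clips) {
    expect_length(clip$samples, round(0.25 * 22050))
    expect_lte(max(abs(clip$samples)), 1)
    expect_true(all(is.finite(clip$samples)))
  }
  ds2 <- generate_audio_dataset(spec)
  expect_identical(ds$clips[[1]]$samples, ds2$clips[[1]]$samples)
})

test_that("invalid audio specs are rejected", {
  expect_error(synthetic_audio_spec(duration_s = 0), "duration_s")
  expect_error(synthetic_audio_spec(sample_rate = -1), "sample_rate")
  expect_error(synthetic_audio_spec(duration_s = 0.01), "shorter")
})

test_that("audio classes separate end to end through extraction and KNN", {
  ds <- generate_audio_dataset(synthetic_audio_spec(
    n_clips_per_class = 20, duration_s = 0.25, seed = 6))
  tab <- build_feature_table(ds$clips, ds$labels)
  # training-set MCC with KNN on all features: signal must be present
  pred <- knn_predict(tab$features, tab$features, tab$labels, k = 5)
  expect_gt(mcc(tab$labels, pred), 0)
})

test_that("WAV files round-trip at 16-bit precision and survive a dataset cycle", {
  clip <- audio_clip(sin(2 * pi * 5 * seq(0, 1, length.out = 4000)), 8000,
                     "tone")
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(clip, path)
  back <- read_wav(path)
  expect_equal(back$sample_rate, 8000)
  expect_lt(max(abs(back$samples - clip$samples)), 1 / 32767)

  ds <- generate_audio_dataset(synthetic_audio_spec(
    n_clips_per_class = 2, duration_s = 0.1, seed = 2))
  dir <- withr::local_tempdir()
  write_audio_dataset(ds, dir)
  back_ds <- read_audio_dataset(dir)
  expect_length(back_ds$clips, 4)
  expect_equal(as.character(back_ds$labels), as.character(ds$labels))
  expect_lt(max(abs(back_ds$clips[[3]]$samples - ds$clips[[3]]$samples)),
            1 / 32767)
})
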