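tiny_cfg <- function(...) {
  benchmark_config(algorithms = c("GA", "EO"),
                   transfer_functions = c("S1", "V2"),
                   n_trials = 2, base_seed = 7,
                   pop_size = 5, n_iterations = 2, ...)
}

tiny_run <- function() {
  tab <- small_table(n_per_class = 20, d = 6, seed = 31)$table
  run_benchmark(tab, tiny_cfg(), quiet = TRUE)
}

test_that("the grid yields |algorithms| x |functions| x trials results", {
  results <- tiny_run()
  expect_length(results, 2 * 2 * 2)
  keys <- vapply(results, `[[`, character(1), "key")
  expect_false(anyDuplicated(keys) > 0)
  for (r in results) {
    expect_lte(r$best$diagnostics$n_selected, 6)
    expect_gte(r$best$diagnostics$n_selected, 1)
    expect_true(all(diff(r$curve) >= 0))
    per_iter <- if (r$algorithm == "TLO") 2L else 1L
    expect_lte(r$n_evaluations, 5 * (1 + per_iter * 2))  # budget contract
  }
})

test_that("re-running with the same base seed is byte-identical", {
  r1 <- tiny_run()
  r2 <- tiny_run()
  p1 <- withr::local_tempfile(fileext = ".jsonl")
  p2 <- withr::local_tempfile(fileext = ".jsonl")
  write_results_jsonl(r1, p1)
  write_results_jsonl(r2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("resume skips completed trials and changes nothing", {
  tab <- small_table(n_per_class = 20, d = 6, seed = 31)$table
  full <- run_benchmark(tab, tiny_cfg(), quiet = TRUE)
  resumed <- run_benchmark(tab, tiny_cfg(), resume = full[1:3], quiet = TRUE)
  expect_equal(length(resumed), length(full))
  k <- vapply(full, `[[`, character(1), "key")
  kr <- vapply(resumed, `[[`, character(1), "key")
  for (key in k) {
    expect_identical(resumed[[which(kr == key)]]$best$fitness,
                     full[[which(k == key)]]$best$fitness)
  }
})

test_that("trial seeds follow the documented base + trial + cell-hash scheme", {
  results <- tiny_run()
  for (r in results) {
    expect_equal(r$seed,
                 (7 + r$trial +
                    respfs:::cell_offset(r$algorithm, r$transfer_function)) %%
                   .Machine$integer.max)
  }
})

test_that("aggregation reproduces hand-computed means and pooling counts", {
  fake <- function(alg, tf, trial, mcc, nsel) {
    list(key = paste(alg, tf, trial, sep = ":"), algorithm = alg,
         transfer_function = tf, trial = trial, seed = 0,
         best = list(fitness = mcc,
                     diagnostics = list(mcc = mcc, n_selected = nsel,
                                        accuracy = 1, balanced_accuracy = 1,
                                        f1_macro = 1)),
         curve = mcc, n_evaluations = 1, elapsed_s = 0)
  }
  results <- list(fake("GA", "S1", 1, 0.5, 10), fake("GA", "S1", 2, 0.7, 20),
                  fake("GA", "V2", 1, 0.9, 3))
  s <- aggregate_benchmark(results)
  cell <- s$per_cell[s$per_cell$transfer_function == "S1", ]
  expect_equal(cell$mean_mcc, 0.6)
  expect_equal(cell$sd_mcc, 0.1)          # population convention
  expect_equal(cell$mean_n_selected, 15)
  single <- s$per_cell[s$per_cell$transfer_function == "V2", ]
  expect_equal(single$sd_mcc, 0)
  fam <- s$per_family
  expect_equal(fam$n[fam$family == "S"], 2)
  expect_equal(fam$n[fam$family == "V"], 1)
  expect_true(all(s$per_cell$best_in_family))   # one cell per family here
  expect_error(aggregate_benchmark(list()), "aggregate|successful")
})

test_that("aggregation is invariant to trial ordering", {
  results <- tiny_run()
  s1 <- aggregate_benchmark(results)
  s2 <- aggregate_benchmark(rev(results))
  expect_equal(s1$per_cell, s2$per_cell)
  expect_equal(s1$per_family, s2$per_family)
})

test_that("reports write the summary CSVs and plots", {
  s <- aggregate_benchmark(tiny_run())
  dir <- withr::local_tempdir()
  files <- report_benchmark(s, dir)
  expect_true(all(file.exists(files)))
  per_cell <- read.csv(file.path(dir, "per_cell.csv"))
  expect_equal(nrow(per_cell), 4)
  expect_true("best_in_family" %in% colnames(per_cell))
})

test_that("config validation rejects empty or unknown grids", {
  expect_error(benchmark_config(transfer_functions = "S9"), "unknown")
  expect_error(benchmark_config(algorithms = character(0)), "non-empty")
  expect_error(benchmark_config(n_trials = 0), "n_trials")
})
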