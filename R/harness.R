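#' Configuration for a full benchmark grid
#'
#' Describes the factorial experiment: algorithms x transfer functions x
#' trials, each trial an independently seeded wrapper feature-selection run
#' on a fixed train/test split. Defaults mirror the emulated study: all six
#' algorithms, all eight transfer functions, 25 trials, population 100, 50
#' iterations.
#'
#' Seeds follow `seed = base_seed + trial_index + cell_offset` where
#' `cell_offset` is a stable hash of the (algorithm, transfer function) key,
#' so cells are independent and a grid is resumable trial by trial.
#'
#' @param algorithms subset of `c("GA","PSO","GWO","TLO","WOA","EO")`.
#' @param transfer_functions subset of [transfer_function_ids()].
#' @param n_trials trials per cell (default 25).
#' @param base_seed integer base seed.
#' @param pop_size,n_iterations optimizer budget (defaults 100, 50).
#' @param split_cfg a [split_spec()].
#' @param fit_cfg a [fitness_config()].
#' @param k KNN neighbourhood size.
#' @param v_rule binarization rule (see [binarize()]).
#' @return An object of class `benchmark_config`.
#' @export
benchmark_config <- function(algorithms = c("GA", "PSO", "GWO", "TLO",
                                            "WOA", "EO"),
                             transfer_functions = transfer_function_ids(),
                             n_trials = 25L, base_seed = 1L,
                             pop_size = 100L, n_iterations = 50L,
                             split_cfg = split_spec(),
                             fit_cfg = fitness_config(),
                             k = 5L, v_rule = "set") {
  if (length(algorithms) == 0 || length(transfer_functions) == 0) {
    stop("algorithm and transfer-function sets must be non-empty")
  }
  algorithms <- match.arg(algorithms,
                          c("GA", "PSO", "GWO", "TLO", "WOA", "EO"),
                          several.ok = TRUE)
  bad <- setdiff(transfer_functions, transfer_function_ids())
  if (length(bad) > 0) stop("unknown transfer functions: ",
                            paste(bad, collapse = ", "))
  if (n_trials < 1) stop("n_trials: must be at least 1")
  structure(list(algorithms = algorithms,
                 transfer_functions = transfer_functions,
                 n_trials = as.integer(n_trials),
                 base_seed = as.integer(base_seed),
                 pop_size = as.integer(pop_size),
                 n_iterations = as.integer(n_iterations),
                 split_cfg = split_cfg, fit_cfg = fit_cfg,
                 k = as.integer(k), v_rule = v_rule),
            class = "benchmark_config")
}

# stable, platform-independent hash of a cell key, below 2^20
cell_offset <- function(algorithm, tf_id) {
  codes <- utf8ToInt(paste0(algorithm, ":", tf_id))
  as.integer(sum(codes * seq_along(codes)) %% 1048576L)
}

trial_seed <- function(cfg, algorithm, tf_id, trial) {
  (cfg$base_seed + trial + cell_offset(algorithm, tf_id)) %%
    .Machine$integer.max
}

#' Run the factorial benchmark grid
#'
#' Executes every (algorithm, transfer function, trial) combination on one
#' fixed split of `table`. Trials already present in `resume` (matched by
#' their `algorithm:transfer_function:trial` key) are reused rather than
#' recomputed. A failing trial is recorded with an `error` field and
#' skipped; a cell in which every trial fails aborts with a summary.
#'
#' @param table a [feature_table()].
#' @param cfg a [benchmark_config()].
#' @param resume optional previous result list to resume from.
#' @param quiet suppress per-cell progress messages.
#' @return List of trial records: `algorithm`, `transfer_function`, `trial`,
#'   `seed`, `best` (mask + metrics), `curve`, `n_evaluations`,
#'   `elapsed_s`.
#' @export
run_benchmark <- function(table, cfg, resume = NULL, quiet = FALSE) {
  stopifnot(inherits(table, "feature_table"),
            inherits(cfg, "benchmark_config"))
  done <- list()
  for (r in resume) done[[r$key]] <- r
  split <- stratified_split(table, cfg$split_cfg)
  results <- list()
  for (alg in cfg$algorithms) {
    for (tf in cfg$transfer_functions) {
      if (!quiet) message("cell ", alg, " x ", tf)
      objective <- make_fs_objective(table, split, tf, cfg$fit_cfg,
                                     k = cfg$k, v_rule = cfg$v_rule)
      n_failed <- 0L
      for (trial in seq_len(cfg$n_trials)) {
        key <- paste(alg, tf, trial, sep = ":")
        if (!is.null(done[[key]])) {
          results[[key]] <- done[[key]]
          next
        }
        seed <- trial_seed(cfg, alg, tf, trial)
        opt_cfg <- optimizer_config(alg, pop_size = cfg$pop_size,
                                    n_iterations = cfg$n_iterations,
                                    seed = seed)
        t0 <- proc.time()[["elapsed"]]
        rec <- tryCatch({
          res <- run_optimizer(objective, ncol(table$features), opt_cfg)
          list(key = key, algorithm = alg, transfer_function = tf,
               trial = trial, seed = seed, best = res$best,
               curve = res$curve, n_evaluations = res$n_evaluations,
               elapsed_s = proc.time()[["elapsed"]] - t0)
        }, error = function(e) {
          list(key = key, algorithm = alg, transfer_function = tf,
               trial = trial, seed = seed, error = conditionMessage(e))
        })
        if (!is.null(rec$error)) n_failed <- n_failed + 1L
        results[[key]] <- rec
      }
      if (n_failed == cfg$n_trials) {
        stop("cell ", alg, " x ", tf, ": all ", cfg$n_trials,
             " trials failed; first error: ",
             results[[paste(alg, tf, 1, sep = ":")]]$error)
      }
    }
  }
  unname(results)
}

trial_frame <- function(results) {
  ok <- Filter(function(r) is.null(r$error), results)
  if (length(ok) == 0) stop("no successful trials to aggregate")
  data.frame(
    algorithm = vapply(ok, `[[`, character(1), "algorithm"),
    transfer_function = vapply(ok, `[[`, character(1), "transfer_function"),
    family = vapply(ok, function(r) tf_family(r$transfer_function),
                    character(1)),
    trial = vapply(ok, `[[`, numeric(1), "trial"),
    seed = vapply(ok, `[[`, numeric(1), "seed"),
    fitness = vapply(ok, function(r) r$best$fitness, numeric(1)),
    mcc = vapply(ok, function(r) r$best$diagnostics$mcc, numeric(1)),
    n_selected = vapply(ok, function(r) r$best$diagnostics$n_selected,
                        numeric(1)),
    accuracy = vapply(ok, function(r) r$best$diagnostics$accuracy,
                      numeric(1)),
    balanced_accuracy = vapply(ok, function(r)
      r$best$diagnostics$balanced_accuracy, numeric(1)),
    f1_macro = vapply(ok, function(r) r$best$diagnostics$f1_macro,
                      numeric(1)),
    stringsAsFactors = FALSE)
}

pop_sd <- function(v) sqrt(mean((v - mean(v))^2))

#' Aggregate benchmark trials per cell and per transfer-function family
#'
#' Produces the two summary layouts of the emulated study: per
#' (algorithm, transfer function) cell, and per (algorithm, family S|V)
#' pooling all of the family's functions x trials (4 x 25 = 100 values per
#' algorithm at the default design). Mean and population standard deviation
#' of both MCC and selected-feature count. The best cell per
#' (algorithm, family) by mean MCC is flagged.
#'
#' @param results output of [run_benchmark()].
#' @return List of class `benchmark_summary`: `per_cell` and `per_family`
#'   data frames, plus `trials` (the flat trial table).
#' @export
aggregate_benchmark <- function(results) {
  df <- trial_frame(results)
  agg <- function(keys) {
    groups <- split(df, df[keys], drop = TRUE)
    out <- do.call(rbind, lapply(groups, function(g) {
      data.frame(g[1, keys, drop = FALSE],
                 n = nrow(g),
                 mean_mcc = mean(g$mcc), sd_mcc = pop_sd(g$mcc),
                 mean_n_selected = mean(g$n_selected),
                 sd_n_selected = pop_sd(g$n_selected),
                 mean_fitness = mean(g$fitness),
                 sd_fitness = pop_sd(g$fitness),
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out[order(out$algorithm), , drop = FALSE]
  }
  per_cell <- agg(c("algorithm", "transfer_function"))
  per_cell$family <- tf_family(per_cell$transfer_function)
  per_cell$best_in_family <- FALSE
  for (g in split(seq_len(nrow(per_cell)),
                  paste(per_cell$algorithm, per_cell$family))) {
    per_cell$best_in_family[g[which.max(per_cell$mean_mcc[g])]] <- TRUE
  }
  structure(list(per_cell = per_cell,
                 per_family = agg(c("algorithm", "family")),
                 trials = df),
            class = "benchmark_summary")
}

#' @export
print.benchmark_summary <- function(x, ...) {
  cat("<benchmark_summary> ", nrow(x$trials), " trials\n", sep = "")
  print(x$per_family, digits = 4)
  invisible(x)
}

#' Write benchmark results as JSON lines
#' @param results output of [run_benchmark()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_results_jsonl <- function(results, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in results) {
    if (is.null(r$error)) {
      r$best$mask_string <- paste(r$best$diagnostics$mask, collapse = "")
      r$best$diagnostics$mask <- NULL
      r$best$position <- NULL
    }
    r$elapsed_s <- NULL   # wall time is hardware noise; keep records seeded

    writeLines(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Write summary CSVs and diagnostic plots for a benchmark
#'
#' Emits `per_cell.csv` and `per_family.csv` (both with a footer-free layout;
#' standard deviations are population form), a fitness-dispersion box plot
#' per algorithm/transfer function, and a selected-feature-count scatter by
#' family — the qualitative pictures the study summarizes.
#'
#' @param summary a `benchmark_summary` from [aggregate_benchmark()].
#' @param out_dir output directory (created if absent).
#' @return Character vector of the files written.
#' @export
report_benchmark <- function(summary, out_dir) {
  stopifnot(inherits(summary, "benchmark_summary"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  f <- file.path(out_dir, "per_cell.csv")
  write.csv(summary$per_cell, f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(out_dir, "per_family.csv")
  write.csv(summary$per_family, f, row.names = FALSE)
  files <- c(files, f)
  df <- summary$trials
  p1 <- ggplot2::ggplot(df, ggplot2::aes(x = .data$transfer_function,
                                         y = .data$fitness)) +
    ggplot2::geom_boxplot(ggplot2::aes(fill = .data$family)) +
    ggplot2::facet_wrap(~algorithm) +
    ggplot2::labs(x = "transfer function", y = "best fitness",
                  title = "Fitness dispersion across trials")
  f <- file.path(out_dir, "fitness_dispersion.pdf")
  suppressMessages(ggplot2::ggsave(f, p1, width = 9, height = 6))
  files <- c(files, f)
  p2 <- ggplot2::ggplot(df, ggplot2::aes(x = .data$transfer_function,
                                         y = .data$n_selected,
                                         colour = .data$family)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, size = 1) +
    ggplot2::facet_wrap(~algorithm) +
    ggplot2::labs(x = "transfer function", y = "selected features",
                  title = "Selected-feature counts by transfer function")
  f <- file.path(out_dir, "selected_features.pdf")
  suppressMessages(ggplot2::ggsave(f, p2, width = 9, height = 6))
  files <- c(files, f)
  files
}
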