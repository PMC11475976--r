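#' Configuration for a continuous metaheuristic run
#'
#' Six population-based maximizers share one interface: GA (real-coded
#' genetic algorithm), PSO (particle swarm), GWO (grey wolf), TLO
#' (teaching-learning-based), WOA (whale optimization) and EO (equilibrium
#' optimizer). All operate on a bounded box and are fully determined by
#' `(algorithm, seed, objective)`.
#'
#' Algorithm parameters (overridable via `params`):
#' * GA: `tournament_size = 2`, `crossover_rate = 0.9`, per-gene mutation
#'   rate `1/D`, `mutation_sd = 0.1 * (ub - lb)`, elitism of 1.
#' * PSO: inertia `w` linear 0.9 to 0.4, `c1 = c2 = 2`, velocity clamp
#'   `0.5 * (ub - lb)`, global-best topology.
#' * GWO: coefficient `a` linear 2 to 0; alpha/beta/delta leader mean.
#' * TLO: teaching factor drawn from \{1, 2\}; greedy acceptance in both
#'   phases (two evaluation rounds per iteration).
#' * WOA: encircle/spiral switch `p = 0.5`, spiral constant `b = 1`,
#'   `a` linear 2 to 0.
#' * EO: pool of 4 best plus mean, `a1 = 2`, `a2 = 1`, `GP = 0.5`.
#'
#' The default box \[-4, 4\] covers the saturation range of all eight
#' transfer functions.
#'
#' @param algorithm one of `"GA"`, `"PSO"`, `"GWO"`, `"TLO"`, `"WOA"`, `"EO"`.
#' @param pop_size population size (default 100).
#' @param n_iterations iteration count (default 50).
#' @param lower_bound,upper_bound box bounds (defaults -4, 4).
#' @param seed integer seed for the whole trajectory.
#' @param params named list of algorithm-specific overrides.
#' @return An object of class `optimizer_config`.
#' @export
optimizer_config <- function(algorithm,
                             pop_size = 100L, n_iterations = 50L,
                             lower_bound = -4, upper_bound = 4,
                             seed = 1L, params = list()) {
  algorithm <- match.arg(algorithm, c("GA", "PSO", "GWO", "TLO", "WOA", "EO"))
  if (pop_size < 2) stop("pop_size: must be at least 2")
  if (n_iterations < 1) stop("n_iterations: must be positive")
  if (lower_bound >= upper_bound) stop("lower_bound must be < upper_bound")
  defaults <- switch(algorithm,
    GA  = list(tournament_size = 2L, crossover_rate = 0.9,
               mutation_sd_frac = 0.1),
    PSO = list(w_start = 0.9, w_end = 0.4, c1 = 2, c2 = 2, v_clamp_frac = 0.5),
    GWO = list(),
    TLO = list(),
    WOA = list(spiral_b = 1),
    EO  = list(a1 = 2, a2 = 1, gp = 0.5))
  params <- utils::modifyList(defaults, params)
  structure(list(algorithm = algorithm, pop_size = as.integer(pop_size),
                 n_iterations = as.integer(n_iterations),
                 lower_bound = lower_bound, upper_bound = upper_bound,
                 seed = as.integer(seed), params = params),
            class = "optimizer_config")
}

#' Sample an initial population uniformly inside the box
#' @param D dimension.
#' @param config an [optimizer_config()] (bounds and pop_size are used).
#' @return `pop_size` x `D` matrix, i.i.d. Uniform(lower, upper). Uses R's
#'   current RNG stream; [run_optimizer()] seeds it from `config$seed`.
#' @export
initialize_population <- function(D, config) {
  matrix(runif(config$pop_size * D, config$lower_bound, config$upper_bound),
         nrow = config$pop_size, ncol = D)
}

clip_box <- function(x, cfg) pmin(pmax(x, cfg$lower_bound), cfg$upper_bound)

# evaluation tracker: counts evaluations, holds the best-ever candidate with
# keep-incumbent tie-breaking, aborts on non-finite objective values.
# Each evaluation passes the move (step) that produced the candidate along
# with the position; objectives that only care about the position (plain
# continuous benchmarks) just take one argument.
new_tracker <- function(objective) {
  tr <- new.env(parent = emptyenv())
  tr$n_evaluations <- 0L
  tr$best_fitness <- -Inf
  tr$best_position <- NULL
  tr$best_diagnostics <- NULL
  takes_step <- length(formals(objective)) >= 2
  tr$eval <- function(x, step = x) {
    res <- if (takes_step) objective(x, step) else objective(x)
    if (is.numeric(res)) res <- list(fitness = res, diagnostics = NULL)
    if (!is.finite(res$fitness)) {
      stop("objective returned a non-finite value at position [",
           paste(signif(x, 4), collapse = ", "), "]")
    }
    tr$n_evaluations <- tr$n_evaluations + 1L
    if (res$fitness > tr$best_fitness) {
      tr$best_fitness <- res$fitness
      tr$best_position <- x
      tr$best_diagnostics <- res$diagnostics
    }
    res$fitness
  }
  tr$eval_rows <- function(P, steps = P) {
    vapply(seq_len(nrow(P)), function(i) tr$eval(P[i, ], steps[i, ]),
           numeric(1))
  }
  tr
}

#' Run a metaheuristic maximizer over a bounded continuous box
#'
#' @param objective function returning either a finite numeric fitness or
#'   `list(fitness = , diagnostics = )`; maximized. A one-argument function
#'   receives the candidate position; a two-argument function additionally
#'   receives the move (step) that produced the candidate — the velocity for
#'   PSO, `child - parent` for GA, `new - old` position otherwise, and the
#'   position itself for the initial population — which is what
#'   transfer-function discretization consumes.
#' @param D problem dimension (>= 1).
#' @param config an [optimizer_config()].
#' @return A list with:
#'   * `best`: list `position`, `fitness`, `diagnostics` (the objective's
#'     diagnostics at the best-ever evaluation, e.g. mask/MCC for the
#'     feature-selection objective),
#'   * `curve`: best-so-far fitness after each iteration (length
#'     `n_iterations`, non-decreasing),
#'   * `n_evaluations`: total objective calls (`pop_size` initial plus at
#'     most `pop_size` per iteration; TLO at most `2 * pop_size`).
#' @export
run_optimizer <- function(objective, D, config) {
  stopifnot(inherits(config, "optimizer_config"), D >= 1)
  withr::with_seed(config$seed, {
    tr <- new_tracker(objective)
    P <- initialize_population(D, config)
    f <- tr$eval_rows(P)
    step <- switch(config$algorithm,
                   GA = step_ga, PSO = step_pso, GWO = step_gwo,
                   TLO = step_tlo, WOA = step_woa, EO = step_eo)
    state <- list()
    curve <- numeric(config$n_iterations)
    for (iter in seq_len(config$n_iterations)) {
      st <- step(P, f, tr, config, iter, state)
      P <- st$P; f <- st$f; state <- st$state
      curve[iter] <- tr$best_fitness
    }
    list(best = list(position = tr$best_position,
                     fitness = tr$best_fitness,
                     diagnostics = tr$best_diagnostics),
         curve = curve,
         n_evaluations = tr$n_evaluations)
  })
}

# ---- per-iteration update rules -------------------------------------------

step_ga <- function(P, f, tr, cfg, iter, state) {
  n <- nrow(P); D <- ncol(P)
  pr <- cfg$params
  mut_sd <- pr$mutation_sd_frac * (cfg$upper_bound - cfg$lower_bound)
  tournament <- function() {
    cand <- sample.int(n, pr$tournament_size)
    cand[which.max(f[cand])]
  }
  elite <- which.max(f)
  newP <- matrix(0, n, D)
  newf <- numeric(n)
  newP[1, ] <- P[elite, ]; newf[1] <- f[elite]      # elitism, not re-evaluated
  for (i in 2:n) {
    p1 <- P[tournament(), ]; p2 <- P[tournament(), ]
    child <- if (runif(1) < pr$crossover_rate) {
      u <- runif(D)
      u * p1 + (1 - u) * p2
    } else p1
    mut <- runif(D) < 1 / D
    child[mut] <- child[mut] + rnorm(sum(mut), sd = mut_sd)
    child <- clip_box(child, cfg)
    newP[i, ] <- child
    newf[i] <- tr$eval(child, child - p1)   # move relative to first parent
  }
  list(P = newP, f = newf, state = state)
}

step_pso <- function(P, f, tr, cfg, iter, state) {
  n <- nrow(P); D <- ncol(P)
  pr <- cfg$params
  if (is.null(state$V)) {
    state$V <- matrix(0, n, D)
    state$pbest <- P; state$pbest_f <- f
    g <- which.max(f)
    state$gbest <- P[g, ]; state$gbest_f <- f[g]
  }
  w <- pr$w_start - (pr$w_start - pr$w_end) * (iter - 1) /
    max(1, cfg$n_iterations - 1)
  vmax <- pr$v_clamp_frac * (cfg$upper_bound - cfg$lower_bound)
  r1 <- matrix(runif(n * D), n); r2 <- matrix(runif(n * D), n)
  state$V <- w * state$V +
    pr$c1 * r1 * (state$pbest - P) +
    pr$c2 * r2 * (matrix(state$gbest, n, D, byrow = TRUE) - P)
  state$V <- pmin(pmax(state$V, -vmax), vmax)
  P <- clip_box(P + state$V, cfg)
  f <- tr$eval_rows(P, state$V)
  improved <- f > state$pbest_f
  state$pbest[improved, ] <- P[improved, , drop = FALSE]
  state$pbest_f[improved] <- f[improved]
  g <- which.max(state$pbest_f)
  if (state$pbest_f[g] > state$gbest_f) {
    state$gbest <- state$pbest[g, ]; state$gbest_f <- state$pbest_f[g]
  }
  list(P = P, f = f, state = state)
}

step_gwo <- function(P, f, tr, cfg, iter, state) {
  n <- nrow(P); D <- ncol(P)
  ord <- order(f, decreasing = TRUE)
  leaders <- P[ord[seq_len(min(3, n))], , drop = FALSE]
  while (nrow(leaders) < 3) leaders <- rbind(leaders, leaders[1, ])
  a <- 2 - 2 * (iter - 1) / max(1, cfg$n_iterations - 1)
  newP <- matrix(0, n, D)
  for (i in seq_len(n)) {
    x <- numeric(D)
    for (l in 1:3) {
      A <- 2 * a * runif(D) - a
      C <- 2 * runif(D)
      dist <- abs(C * leaders[l, ] - P[i, ])
      x <- x + (leaders[l, ] - A * dist)
    }
    newP[i, ] <- clip_box(x / 3, cfg)
  }
  f <- tr$eval_rows(newP, newP - P)
  list(P = newP, f = f, state = state)
}

step_tlo <- function(P, f, tr, cfg, iter, state) {
  n <- nrow(P); D <- ncol(P)
  # teacher phase
  teacher <- P[which.max(f), ]
  mean_pos <- colMeans(P)
  for (i in seq_len(n)) {
    tf <- sample(1:2, 1)
    cand <- clip_box(P[i, ] + runif(D) * (teacher - tf * mean_pos), cfg)
    fc <- tr$eval(cand, cand - P[i, ])
    if (fc > f[i]) { P[i, ] <- cand; f[i] <- fc }
  }
  # learner phase
  for (i in seq_len(n)) {
    j <- sample(seq_len(n)[-i], 1)
    dir <- if (f[i] >= f[j]) P[i, ] - P[j, ] else P[j, ] - P[i, ]
    cand <- clip_box(P[i, ] + runif(D) * dir, cfg)
    fc <- tr$eval(cand, cand - P[i, ])
    if (fc > f[i]) { P[i, ] <- cand; f[i] <- fc }
  }
  list(P = P, f = f, state = state)
}

step_woa <- function(P, f, tr, cfg, iter, state) {
  n <- nrow(P); D <- ncol(P)
  b <- cfg$params$spiral_b
  best <- P[which.max(f), ]
  a <- 2 - 2 * (iter - 1) / max(1, cfg$n_iterations - 1)
  newP <- matrix(0, n, D)
  for (i in seq_len(n)) {
    if (runif(1) < 0.5) {
      # scalar A and C per whale, as in the canonical formulation
      A <- 2 * a * runif(1) - a
      C <- 2 * runif(1)
      target <- if (abs(A) >= 1) P[sample.int(n, 1), ] else best
      newP[i, ] <- target - A * abs(C * target - P[i, ])
    } else {
      l <- runif(1, -1, 1)
      newP[i, ] <- abs(best - P[i, ]) * exp(b * l) * cos(2 * pi * l) + best
    }
    newP[i, ] <- clip_box(newP[i, ], cfg)
  }
  f <- tr$eval_rows(newP, newP - P)
  list(P = newP, f = f, state = state)
}

step_eo <- function(P, f, tr, cfg, iter, state) {
  n <- nrow(P); D <- ncol(P)
  pr <- cfg$params
  if (is.null(state$pool)) { state$pool <- NULL; state$pool_f <- NULL }
  # refresh the equilibrium pool with the current generation's best four
  all_P <- rbind(state$pool, P)
  all_f <- c(state$pool_f, f)
  ord <- order(all_f, decreasing = TRUE)
  keep <- ord[seq_len(min(4, length(all_f)))]
  state$pool <- all_P[keep, , drop = FALSE]
  state$pool_f <- all_f[keep]
  pool <- rbind(state$pool, colMeans(state$pool))
  t_par <- (1 - iter / cfg$n_iterations)^(pr$a2 * iter / cfg$n_iterations)
  newP <- matrix(0, n, D)
  for (i in seq_len(n)) {
    ceq <- pool[sample.int(nrow(pool), 1), ]
    lambda <- runif(D)
    r <- runif(D)
    F_ <- pr$a1 * sign(r - 0.5) * (exp(-lambda * t_par) - 1)
    r1 <- runif(1); r2 <- runif(1)
    gcp <- if (r2 >= pr$gp) 0.5 * r1 else 0
    g0 <- gcp * (ceq - lambda * P[i, ])
    newP[i, ] <- clip_box(
      ceq + (P[i, ] - ceq) * F_ + (g0 / lambda) * (1 - F_), cfg)
  }
  f <- tr$eval_rows(newP, newP - P)
  list(P = newP, f = f, state = state)
}
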