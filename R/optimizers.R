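#' Binarize a continuous search position into a feature mask
#'
#' Strict threshold: component `j` selects feature `j` iff its value exceeds
#' 0.5; a value of exactly 0.5 maps to 0 (not selected).
#'
#' @param position Numeric vector with finite components in `[0, 1]`.
#' @return Integer 0/1 mask of the same length.
#' @examples
#' binarize(c(0.7, 0.5, 0.2))
#' @export
binarize <- function(position) {
  if (any(!is.finite(position))) stop("position contains non-finite values")
  as.integer(position > 0.5)
}

#' Configuration for the mask-search metaheuristics
#'
#' Shared settings for grey wolf optimization (`"gwo"`), binary particle swarm
#' (`"pso"`) and a genetic algorithm (`"ga"`). Defaults are a swarm of 25
#' agents run for 100 iterations on the `[0, 1]^n` box.
#'
#' @param algorithm `"gwo"`, `"pso"` or `"ga"`.
#' @param pop_size Population size (default 25; GWO needs `>= 3`).
#' @param max_iters Iteration budget (default 100).
#' @param seed Master seed; all draws derive from it in a fixed documented
#'   order so runs are reproducible.
#' @param leader_retention `"best_so_far"` (default: alpha/beta/delta only
#'   replaced by strictly better agents, giving a monotone convergence curve)
#'   or `"per_iteration"` (leaders re-selected fresh each iteration).
#' @param pso List of PSO parameters: `c1`, `c2` (both 2.0), `w_max` (0.9),
#'   `w_min` (0.4) for the linear inertia schedule, `v_max` (0.6).
#' @param ga List of GA parameters: `crossover_rate` (0.8, single point),
#'   `mutation_rate` (`NULL` = 1/n per bit), `tournament_size` (2),
#'   `elitism` (1).
#' @return An object of class `optimizer_config`.
#' @export
optimizer_config <- function(algorithm = c("gwo", "pso", "ga"),
                             pop_size = 25L, max_iters = 100L, seed = 1L,
                             leader_retention = c("best_so_far", "per_iteration"),
                             pso = list(), ga = list()) {
  algorithm <- match.arg(algorithm)
  pop_size <- as.integer(pop_size)
  max_iters <- as.integer(max_iters)
  if (is.na(pop_size) || pop_size < 2L) stop("pop_size must be at least 2")
  if (algorithm == "gwo" && pop_size < 3L) {
    stop("gwo needs pop_size >= 3 (three leaders)")
  }
  if (is.na(max_iters) || max_iters < 1L) stop("max_iters must be at least 1")
  pso_def <- list(c1 = 2.0, c2 = 2.0, w_max = 0.9, w_min = 0.4, v_max = 0.6)
  ga_def <- list(crossover_rate = 0.8, mutation_rate = NULL,
                 tournament_size = 2L, elitism = 1L)
  structure(
    list(algorithm = algorithm, pop_size = pop_size, max_iters = max_iters,
         lb = 0, ub = 1, seed = as.integer(seed),
         leader_retention = match.arg(leader_retention),
         pso = utils::modifyList(pso_def, pso),
         ga = utils::modifyList(ga_def, ga)),
    class = "optimizer_config"
  )
}

# Normalize a user fitness result into the canonical fitness-value list.
# Fitness functions may return a bare number or a list with at least $f
# (optionally $f1, $f2, $selected_count). Non-finite fitness is treated as
# the worst possible value so the search survives degenerate masks.
as_fitness_value <- function(r, mask) {
  if (is.numeric(r)) r <- list(f = as.double(r[[1L]]))
  f <- as.double(r$f %||% -Inf)
  if (!is.finite(f)) f <- -Inf
  list(
    f = f,
    f1 = as.double(r$f1 %||% NA_real_),
    f2 = as.double(r$f2 %||% NA_real_),
    selected_count = as.integer(r$selected_count %||% sum(mask))
  )
}

call_fitness <- function(fitness_fn, mask, wolf, iter) {
  r <- if (length(formals(fitness_fn)) >= 2L) {
    fitness_fn(mask, list(agent = wolf, iter = iter))
  } else {
    fitness_fn(mask)
  }
  as_fitness_value(r, mask)
}

history_row <- function(iter, best) {
  data.frame(
    iteration = iter, best_f = best$fit$f, best_f1 = best$fit$f1,
    best_f2 = best$fit$f2, selected_count = best$fit$selected_count
  )
}

#' Search for the best binary feature mask
#'
#' Runs the configured metaheuristic (GWO, PSO or GA) to maximize
#' `fitness_fn` over 0/1 masks of length `n_features`. GWO and PSO search the
#' continuous box `[0, 1]^n` and binarize at the strict 0.5 threshold for
#' every fitness evaluation and for the final answer; the GA works directly
#' on bitstrings. All three share the same fitness interface, so a fitness
#' written for one runs unchanged against the others.
#'
#' `fitness_fn` takes a 0/1 integer mask (and optionally an info list with
#' `$agent` and `$iter`, used e.g. to derive per-evaluation child seeds) and
#' returns either a single number or a list with fields `f` (maximized),
#' and optionally `f1`, `f2`, `selected_count` for the convergence log.
#'
#' @param fitness_fn Fitness function as described above.
#' @param n_features Mask length (`>= 1`).
#' @param config An [optimizer_config()].
#' @return A list with `mask` (best 0/1 mask), `fitness` (its fitness-value
#'   list), `history` (data frame: iteration, best_f, best_f1, best_f2,
#'   selected_count — best-so-far per iteration), `n_evals`, and `algorithm`.
#' @examples
#' res <- optimize_mask(function(m) sum(m) / 5, 5,
#'                      optimizer_config("gwo", pop_size = 5, max_iters = 10))
#' res$mask
#' @export
optimize_mask <- function(fitness_fn, n_features, config = optimizer_config()) {
  stopifnot(inherits(config, "optimizer_config"))
  n_features <- as.integer(n_features)
  if (is.na(n_features) || n_features < 1L) stop("n_features must be >= 1")
  with_seed(config$seed, {
    switch(config$algorithm,
      gwo = gwo_search(fitness_fn, n_features, config),
      pso = pso_search(fitness_fn, n_features, config),
      ga = ga_search(fitness_fn, n_features, config)
    )
  })
}

# Grey wolf optimization over [0,1]^n. Per iteration: clamp, binarize and
# evaluate every wolf; update the alpha/beta/delta leaders; decay the control
# parameter a linearly from 2 to 0 (a = 0 exactly at the final iteration);
# move every wolf to the mean of the three leader-guided candidates
# X_k = X_leader - A_k * |C_k * X_leader - X| with A = 2*a*r1 - a, C = 2*r2,
# r1/r2 drawn per wolf and dimension (leader-major order: all alpha draws,
# then beta, then delta; r1 before r2).
gwo_search <- function(fitness_fn, n, cfg) {
  pop <- cfg$pop_size
  X <- matrix(stats::runif(pop * n, cfg$lb, cfg$ub), pop, n)
  empty <- list(position = NULL, fit = list(f = -Inf, f1 = NA_real_,
                                            f2 = NA_real_, selected_count = NA_integer_))
  alpha <- beta <- delta <- empty
  best <- empty # overall best (equals alpha under best-so-far retention)
  history <- vector("list", cfg$max_iters)
  n_evals <- 0L
  for (t in seq_len(cfg$max_iters)) {
    if (cfg$leader_retention == "per_iteration") {
      alpha <- beta <- delta <- empty
    }
    for (i in seq_len(pop)) {
      X[i, ] <- pmin(pmax(X[i, ], cfg$lb), cfg$ub)
      fit <- call_fitness(fitness_fn, binarize(X[i, ]), i, t)
      n_evals <- n_evals + 1L
      agent <- list(position = X[i, ], fit = fit)
      # strict improvement => earlier-evaluated agent wins fitness ties
      if (fit$f > alpha$fit$f) {
        delta <- beta; beta <- alpha; alpha <- agent
      } else if (fit$f > beta$fit$f) {
        delta <- beta; beta <- agent
      } else if (fit$f > delta$fit$f) {
        delta <- agent
      }
      if (fit$f > best$fit$f) best <- agent
    }
    history[[t]] <- history_row(t, best)
    a <- 2 - t * (2 / cfg$max_iters)
    leaders <- list(alpha, beta, delta)
    cand <- matrix(0, pop, n)
    for (l in 1:3) {
      lead <- leaders[[l]]
      pos <- if (is.null(lead$position)) alpha$position else lead$position
      R1 <- matrix(stats::runif(pop * n), pop, n)
      R2 <- matrix(stats::runif(pop * n), pop, n)
      A <- 2 * a * R1 - a
      C <- 2 * R2
      Xl <- matrix(pos, pop, n, byrow = TRUE)
      D <- abs(C * Xl - X)
      cand <- cand + (Xl - A * D)
    }
    X <- cand / 3
  }
  list(mask = binarize(best$position), fitness = best$fit,
       history = do.call(rbind, history), n_evals = n_evals,
       algorithm = "gwo")
}

# Global-best binary PSO: continuous positions/velocities on [0,1]^n, linear
# inertia w_max -> w_min, velocity clamp at +/- v_max, positions clamped to
# the box, Eq-4-style strict binarization at fitness evaluation.
pso_search <- function(fitness_fn, n, cfg) {
  pop <- cfg$pop_size
  p <- cfg$pso
  X <- matrix(stats::runif(pop * n, cfg$lb, cfg$ub), pop, n)
  V <- matrix(0, pop, n)
  pbest_pos <- X
  pbest_f <- rep(-Inf, pop)
  gbest <- list(position = NULL, fit = list(f = -Inf, f1 = NA_real_,
                                            f2 = NA_real_, selected_count = NA_integer_))
  history <- vector("list", cfg$max_iters)
  n_evals <- 0L
  for (t in seq_len(cfg$max_iters)) {
    for (i in seq_len(pop)) {
      fit <- call_fitness(fitness_fn, binarize(X[i, ]), i, t)
      n_evals <- n_evals + 1L
      if (fit$f > pbest_f[i]) {
        pbest_f[i] <- fit$f
        pbest_pos[i, ] <- X[i, ]
      }
      if (fit$f > gbest$fit$f) gbest <- list(position = X[i, ], fit = fit)
    }
    history[[t]] <- history_row(t, gbest)
    w <- p$w_max - (p$w_max - p$w_min) * t / cfg$max_iters
    R1 <- matrix(stats::runif(pop * n), pop, n)
    R2 <- matrix(stats::runif(pop * n), pop, n)
    G <- matrix(gbest$position, pop, n, byrow = TRUE)
    V <- w * V + p$c1 * R1 * (pbest_pos - X) + p$c2 * R2 * (G - X)
    V <- pmin(pmax(V, -p$v_max), p$v_max)
    X <- pmin(pmax(X + V, cfg$lb), cfg$ub)
  }
  list(mask = binarize(gbest$position), fitness = gbest$fit,
       history = do.call(rbind, history), n_evals = n_evals,
       algorithm = "pso")
}

# Generational GA on bitstrings: tournament selection, single-point
# crossover, per-bit mutation (default rate 1/n), elitism.
ga_search <- function(fitness_fn, n, cfg) {
  pop <- cfg$pop_size
  g <- cfg$ga
  mut <- g$mutation_rate %||% (1 / n)
  P <- matrix(as.integer(stats::runif(pop * n) > 0.5), pop, n)
  best <- list(position = NULL, fit = list(f = -Inf, f1 = NA_real_,
                                           f2 = NA_real_, selected_count = NA_integer_))
  history <- vector("list", cfg$max_iters)
  n_evals <- 0L
  for (t in seq_len(cfg$max_iters)) {
    fits <- numeric(pop)
    for (i in seq_len(pop)) {
      fit <- call_fitness(fitness_fn, P[i, ], i, t)
      n_evals <- n_evals + 1L
      fits[i] <- fit$f
      if (fit$f > best$fit$f) best <- list(position = P[i, ], fit = fit)
    }
    history[[t]] <- history_row(t, best)
    tournament <- function() {
      contenders <- sample.int(pop, g$tournament_size, replace = TRUE)
      contenders[which.max(fits[contenders])]
    }
    newP <- matrix(0L, pop, n)
    n_elite <- min(g$elitism, pop)
    if (n_elite > 0L) {
      ord <- order(fits, decreasing = TRUE)
      newP[seq_len(n_elite), ] <- P[ord[seq_len(n_elite)], , drop = FALSE]
    }
    i <- n_elite
    while (i < pop) {
      pa <- P[tournament(), ]
      pb <- P[tournament(), ]
      if (stats::runif(1) < g$crossover_rate && n > 1L) {
        cut <- sample.int(n - 1L, 1L)
        child1 <- c(pa[seq_len(cut)], pb[(cut + 1L):n])
        child2 <- c(pb[seq_len(cut)], pa[(cut + 1L):n])
      } else {
        child1 <- pa
        child2 <- pb
      }
      for (child in list(child1, child2)) {
        if (i >= pop) break
        flip <- stats::runif(n) < mut
        child[flip] <- 1L - child[flip]
        i <- i + 1L
        newP[i, ] <- child
      }
    }
    P <- newP
  }
  list(mask = as.integer(best$position), fitness = best$fit,
       history = do.call(rbind, history), n_evals = n_evals,
       algorithm = "ga")
}

#' Write a convergence history as TSV
#'
#' @param result A result from [optimize_mask()] or [select_features()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_history <- function(result, path) {
  utils::write.table(result$history, path,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
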