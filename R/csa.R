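#' Configuration for the crow search algorithm
#'
#' The crow search algorithm (CSA) is a population metaheuristic for
#' bound-constrained global optimization: each of N "crows" remembers the
#' best position it has found, and on every iteration either follows a
#' randomly chosen flockmate's memory (step scaled by the flight length
#' \code{fl}) or, with the awareness probability \code{ap}, restarts at a
#' uniform random point of the search box.
#'
#' The canonical hyperparameter values \code{n_crows = 50}, \code{fl = 2},
#' \code{ap = 0.1} are the defaults; all are overridable.
#'
#' @param bounds 2 x d numeric matrix of box bounds (row 1 = lower,
#'   row 2 = upper).
#' @param n_crows Flock size N (at least 2).
#' @param fl Flight length (positive step-size multiplier).
#' @param ap Awareness probability in \eqn{[0, 1]}.
#' @param iter_max Number of iterations (at least 1).
#' @param seed Integer seed; every random draw in a run derives from it.
#' @param n_runs Number of independent repeats for [csa_multirun()].
#' @return A validated \code{csa_config} list.
#' @export
csa_config <- function(bounds, n_crows = 50L, fl = 2, ap = 0.1,
                       iter_max = 150L, seed = 0L, n_runs = 1L) {
  bounds <- as.matrix(bounds)
  if (nrow(bounds) != 2L || any(!is.finite(bounds)) ||
      any(bounds[1L, ] >= bounds[2L, ])) {
    stop("bounds must be a 2 x d matrix with lower < upper")
  }
  n_crows <- as.integer(n_crows)
  iter_max <- as.integer(iter_max)
  n_runs <- as.integer(n_runs)
  if (n_crows < 2L) stop("flock size must be at least 2")
  if (!(fl > 0)) stop("flight length must be positive")
  if (ap < 0 || ap > 1) stop("awareness probability must be in [0, 1]")
  if (iter_max < 1L) stop("iter_max must be at least 1")
  if (n_runs < 1L) stop("n_runs must be at least 1")
  structure(list(bounds = bounds, n_crows = n_crows, fl = fl, ap = ap,
                 iter_max = iter_max, seed = as.integer(seed),
                 n_runs = n_runs),
            class = "csa_config")
}

#' Pursuit move of a crow toward a flockmate's memory
#'
#' The deterministic part of the CSA position update: from position \code{x},
#' a crow following the memorized position \code{mem_j} of crow j moves to
#' \eqn{x + r \cdot fl \cdot (mem_j - x)} with \eqn{r \sim U(0,1)}.
#'
#' @param x Current position (numeric vector).
#' @param mem_j Followed memory (same length).
#' @param r Uniform random draw(s) in \eqn{[0,1]}.
#' @param fl Flight length.
#' @return The new (unclamped) position.
#' @examples
#' csa_move(0, 1, r = 0.5, fl = 2)  # 1
#' @export
csa_move <- function(x, mem_j, r, fl) {
  x + r * fl * (mem_j - x)
}

# One CSA iteration over the whole flock (vectorized across crows).
# state: list(positions, memories, mem_fit). Uses the current RNG stream.
csa_step <- function(state, objective, config) {
  n <- config$n_crows
  d <- ncol(config$bounds)
  lo <- config$bounds[1L, ]
  hi <- config$bounds[2L, ]
  j <- sample.int(n, n, replace = TRUE)
  r_j <- stats::runif(n)
  follow <- r_j >= config$ap
  r_i <- stats::runif(n)
  newpos <- state$positions
  if (any(follow)) {
    idx <- which(follow)
    newpos[idx, ] <- csa_move(state$positions[idx, , drop = FALSE],
                              state$memories[j[idx], , drop = FALSE],
                              r_i[idx], config$fl)
  }
  if (any(!follow)) {
    idx <- which(!follow)
    newpos[idx, ] <- matrix(stats::runif(length(idx) * d), ncol = d) %*%
      diag(hi - lo, d) + matrix(lo, length(idx), d, byrow = TRUE)
  }
  # clamp to the box component-wise
  newpos <- pmin(pmax(newpos, matrix(lo, n, d, byrow = TRUE)),
                 matrix(hi, n, d, byrow = TRUE))
  fit <- apply(newpos, 1L, objective)
  if (any(!is.finite(fit))) {
    bad <- which(!is.finite(fit))[1L]
    stop("objective returned a non-finite value at (",
         paste(signif(newpos[bad, ], 6), collapse = ", "), ")")
  }
  better <- fit > state$mem_fit  # strictly better; ties keep the old memory
  state$positions <- newpos
  state$memories[better, ] <- newpos[better, , drop = FALSE]
  state$mem_fit[better] <- fit[better]
  state
}

#' Maximize an objective with the crow search algorithm
#'
#' Seeded, reproducible run: the flock is initialized uniformly in the search
#' box with each crow's memory set to its starting position, then
#' \code{iter_max} flock updates are applied (see [csa_config()] for the move
#' rule). Positions leaving the box are clamped component-wise; a memory is
#' replaced only by a strictly better position, so the best-so-far trace is
#' non-decreasing.
#'
#' @param objective Function of one in-bounds numeric vector returning a
#'   finite scalar to be maximized.
#' @param config A [csa_config()].
#' @return A \code{csa_result}: list with \code{best_position},
#'   \code{best_fitness}, \code{trace} (best-so-far fitness per iteration),
#'   and \code{config}.
#' @examples
#' cfg <- csa_config(rbind(rep(-1, 3), rep(1, 3)), iter_max = 50, seed = 1)
#' csa_optimize(function(x) -sum(x^2), cfg)$best_fitness  # near 0
#' @export
csa_optimize <- function(objective, config) {
  stopifnot(inherits(config, "csa_config"), is.function(objective))
  set.seed(config$seed)
  n <- config$n_crows
  d <- ncol(config$bounds)
  lo <- config$bounds[1L, ]
  hi <- config$bounds[2L, ]
  positions <- matrix(stats::runif(n * d), ncol = d) %*% diag(hi - lo, d) +
    matrix(lo, n, d, byrow = TRUE)
  fit <- apply(positions, 1L, objective)
  if (any(!is.finite(fit))) {
    bad <- which(!is.finite(fit))[1L]
    stop("objective returned a non-finite value at (",
         paste(signif(positions[bad, ], 6), collapse = ", "), ")")
  }
  state <- list(positions = positions, memories = positions, mem_fit = fit)
  trace <- numeric(config$iter_max)
  for (it in seq_len(config$iter_max)) {
    state <- csa_step(state, objective, config)
    trace[it] <- max(state$mem_fit)
  }
  best <- which.max(state$mem_fit)
  structure(list(best_position = state$memories[best, ],
                 best_fitness = state$mem_fit[best],
                 trace = trace,
                 config = config),
            class = "csa_result")
}

#' Repeated CSA runs with spread statistics
#'
#' Runs [csa_optimize()] \code{n_runs} times with per-run seeds derived
#' deterministically from the master seed (\code{seed + run index}) and
#' summarizes the per-run best fitnesses by their best, worst, mean and
#' standard deviation — the usual robustness report for a stochastic
#' optimizer.
#'
#' @param objective Objective function (maximized).
#' @param config A [csa_config()] with \code{n_runs >= 2}.
#' @return A \code{csa_result} for the best run, with extra fields
#'   \code{run_best} (per-run best fitnesses) and \code{stats}
#'   (best/worst/mean/std).
#' @export
csa_multirun <- function(objective, config) {
  stopifnot(inherits(config, "csa_config"))
  if (config$n_runs < 2L) stop("multi-run statistics need n_runs >= 2")
  runs <- lapply(seq_len(config$n_runs), function(k) {
    cfg_k <- config
    cfg_k$seed <- config$seed + k
    csa_optimize(objective, cfg_k)
  })
  run_best <- vapply(runs, `[[`, numeric(1L), "best_fitness")
  out <- runs[[which.max(run_best)]]
  out$run_best <- run_best
  out$stats <- c(best = max(run_best), worst = min(run_best),
                 mean = mean(run_best), std = stats::sd(run_best))
  out$config <- config
  out
}

#' @export
print.csa_result <- function(x, ...) {
  cat("Crow search result\n")
  cat("  best position:", paste(sprintf("%.4f", x$best_position),
                                collapse = ", "), "\n")
  cat(sprintf("  best fitness:  %.6f after %d iterations\n",
              x$best_fitness, length(x$trace)))
  if (!is.null(x$stats)) {
    cat(sprintf("  over %d runs: best %.6f, worst %.6f, mean %.6f, std %.3g\n",
                length(x$run_best), x$stats["best"], x$stats["worst"],
                x$stats["mean"], x$stats["std"]))
  }
  invisible(x)
}

#' Write a CSA convergence trace as two-column delimited text
#'
#' @param result A \code{csa_result}.
#' @param path Output path (columns: iteration, best fitness so far).
#' @return \code{path}, invisibly.
#' @export
write_trace <- function(result, path) {
  utils::write.csv(data.frame(iteration = seq_along(result$trace),
                              best_fitness = result$trace),
                   path, row.names = FALSE)
  invisible(path)
}
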