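#' Individual desirability of a response (maximize goal)
#'
#' Derringer-type one-sided desirability for a larger-is-better response:
#' \deqn{d = 0 \; (y < L), \quad ((y - L)/(U - L))^w \; (L \le y \le U),
#'       \quad 1 \; (y > U)}
#' where \eqn{L} is the lowest acceptable response, \eqn{U} the value beyond
#' which no further gain matters, and \eqn{w > 0} the weight exponent shaping
#' the ramp.
#'
#' @param y Numeric response value(s).
#' @param lower,upper Bounds \eqn{L < U} in response units.
#' @param weight Weight exponent \eqn{w > 0} (default 1, linear ramp).
#' @return Desirabilities in \eqn{[0, 1]}, same length as \code{y}.
#' @examples
#' d_single(99.5373, lower = 64.88, upper = 100)  # 0.9868
#' @export
d_single <- function(y, lower, upper, weight = 1) {
  stopifnot(is.numeric(y), is.numeric(lower), is.numeric(upper),
            length(lower) == 1L, length(upper) == 1L, length(weight) == 1L)
  if (!(lower < upper)) stop("desirability bounds require lower < upper")
  if (!(weight > 0)) stop("desirability weight must be positive")
  d <- ((y - lower) / (upper - lower))
  d <- pmin(pmax(d, 0), 1)^weight
  d
}

#' Composite desirability
#'
#' Geometric mean of individual desirabilities,
#' \eqn{D = (d_1 d_2 \cdots d_n)^{1/n}}. With a single response \eqn{D = d};
#' any zero component makes \eqn{D = 0}.
#'
#' @param d Numeric vector of desirabilities, each in \eqn{[0, 1]}.
#' @return The composite desirability \eqn{D}.
#' @export
d_composite <- function(d) {
  if (length(d) == 0L) stop("composite desirability needs at least one response")
  if (any(d < 0 | d > 1)) stop("desirabilities must lie in [0, 1]")
  if (any(d == 0)) return(0)
  exp(mean(log(d)))
}

#' Locate the most desirable operating point of a fitted surface
#'
#' Maximizes the composite desirability of the model-predicted response over
#' a coded box (default the design cube \eqn{[-1,1]^d}). The search is
#' deterministic: a dense grid scan (first-encountered maximum in row-major
#' order wins ties) followed by a box-constrained quasi-Newton polish started
#' from the best grid cell. Because the maximize-goal desirability is
#' non-decreasing in the predicted response, maximizing \eqn{D} is equivalent
#' to maximizing predicted \eqn{y}; the polish therefore optimizes the
#' predicted response directly and \eqn{d}, \eqn{D} are evaluated at the
#' optimum.
#'
#' @param model A \code{quadratic_model}.
#' @param lower,upper Desirability bounds \eqn{L}, \eqn{U} in response units.
#' @param weight Desirability weight exponent (default 1).
#' @param bounds 2 x d matrix (rows: min, max) of coded search bounds, or
#'   \code{NULL} for \eqn{[-1,1]^d}.
#' @param grid_step Grid spacing of the scan (default 0.01).
#' @param factors Optional list of [factor_spec()] to decode the optimum into
#'   actual units.
#' @return An \code{optimum_report}: list with \code{coded}, \code{actual}
#'   (if factors supplied), \code{predicted}, \code{d}, \code{D}.
#' @examples
#' fit <- fit_quadratic(pb_design())
#' maximize_desirability(fit$model, lower = 64.88, upper = 100,
#'                       factors = pb_design()$factors)
#' @export
maximize_desirability <- function(model, lower, upper, weight = 1,
                                  bounds = NULL, grid_step = 0.01,
                                  factors = NULL) {
  stopifnot(inherits(model, "quadratic_model"))
  d <- length(model$factors)
  if (is.null(bounds)) bounds <- rbind(rep(-1, d), rep(1, d))
  bounds <- as.matrix(bounds)
  stopifnot(nrow(bounds) == 2L, ncol(bounds) == d, all(bounds[1L, ] < bounds[2L, ]))

  best <- grid_argmax(model, bounds, grid_step)
  opt <- stats::optim(best$point,
                      fn = function(x) -predict_quiet(model, x),
                      method = "L-BFGS-B",
                      lower = bounds[1L, ], upper = bounds[2L, ],
                      control = list(factr = 1e4))
  coded <- pmin(pmax(opt$par, bounds[1L, ]), bounds[2L, ])
  # keep whichever of grid cell / polished point predicts higher
  if (-opt$value < best$value) coded <- best$point
  names(coded) <- model$factors
  pred <- predict_quiet(model, coded)
  di <- d_single(pred, lower, upper, weight)
  report <- list(coded = coded,
                 predicted = pred,
                 d = di,
                 D = d_composite(di),
                 lower = lower, upper = upper, weight = weight)
  if (!is.null(factors)) {
    report$actual <- mapply(function(f, c) to_actual(f, c), factors, coded)
    names(report$actual) <- vapply(factors, `[[`, character(1L), "name")
  }
  structure(report, class = "optimum_report")
}

# predict() without the extrapolation message (search stays inside bounds;
# tiny numerical overshoot should not chatter).
predict_quiet <- function(model, x) {
  suppressMessages(predict(model, x))
}

# Row-major dense grid argmax, chunked over the first coordinate so the full
# basis matrix is never materialized. Strict > keeps the first-encountered
# maximum, making tie-breaking deterministic.
grid_argmax <- function(model, bounds, step) {
  d <- length(model$factors)
  axes <- lapply(seq_len(d), function(i) {
    seq(bounds[1L, i], bounds[2L, i], by = step)
  })
  tail_grid <- as.matrix(do.call(expand.grid, rev(axes[-1L])))[, rev(seq_len(d - 1L)), drop = FALSE]
  best_val <- -Inf
  best_pt <- NULL
  for (a in axes[[1L]]) {
    pts <- cbind(a, tail_grid)
    vals <- predict_quiet(model, pts)
    i <- which.max(vals)
    if (vals[i] > best_val) {
      best_val <- vals[i]
      best_pt <- as.numeric(pts[i, ])
    }
  }
  list(point = best_pt, value = best_val)
}

#' @export
print.optimum_report <- function(x, ...) {
  cat("Desirability optimum\n")
  cat("  coded:    ", paste(sprintf("%s = %.4f", names(x$coded), x$coded),
                            collapse = ", "), "\n")
  if (!is.null(x$actual)) {
    cat("  actual:   ", paste(sprintf("%s = %.4g", names(x$actual), x$actual),
                              collapse = ", "), "\n")
  }
  cat(sprintf("  predicted response: %.4f\n", x$predicted))
  cat(sprintf("  desirability d = %.4f, composite D = %.4f\n", x$d, x$D))
  invisible(x)
}

#' Write an optimum report as key-value text
#'
#' @param report An \code{optimum_report} (or the result of [csa_optimize()]).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_optimum <- function(report, path) {
  kv <- c(sprintf("coded_%s=%.17g", names(report$coded), report$coded))
  if (!is.null(report$actual)) {
    kv <- c(kv, sprintf("actual_%s=%.17g", names(report$actual), report$actual))
  }
  kv <- c(kv, sprintf("predicted=%.17g", report$predicted))
  if (!is.null(report$D)) {
    kv <- c(kv, sprintf("d=%.17g", report$d), sprintf("D=%.17g", report$D))
  }
  writeLines(kv, path)
  invisible(path)
}
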