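# Build a 3-factor quadratic_model from a length-10 coefficient vector in
# canonical term order (intercept, A, B, C, A*A, B*B, C*C, A*B, A*C, B*C).
make_surface <- function(coefs, factors = c("x1", "x2", "x3")) {
  names(coefs) <- c("(Intercept)", "A", "B", "C",
                    "A*A", "B*B", "C*C", "A*B", "A*C", "B*C")
  structure(list(coef = coefs, factors = factors,
                 residual_df = NA_integer_, residual_ss = NA_real_),
            class = "quadratic_model")
}

# Analytic stationary point of the quadratic surface restricted to the plane
# where factor `hold` is fixed at `at`: solves the 2x2 linear system from the
# gradient of the two free factors. Independent oracle for optimizer tests.
slice_stationary <- function(model, hold, at = 0) {
  b <- model$coef
  lin <- b[2:4]
  H <- matrix(c(2 * b["A*A"], b["A*B"], b["A*C"],
                b["A*B"], 2 * b["B*B"], b["B*C"],
                b["A*C"], b["B*C"], 2 * b["C*C"]), 3, 3)
  free <- setdiff(1:3, hold)
  rhs <- -(lin[free] + H[free, hold] * at)
  solve(H[free, free], rhs)
}

# Full-cube stationary point (all three factors free).
full_stationary <- function(model) {
  b <- model$coef
  H <- matrix(c(2 * b["A*A"], b["A*B"], b["A*C"],
                b["A*B"], 2 * b["B*B"], b["B*C"],
                b["A*C"], b["B*C"], 2 * b["C*C"]), 3, 3)
  solve(H, -b[2:4])
}

# Exhaustive grid maximum of a model over [-1,1]^3, chunked by the first
# coordinate; brute-force oracle, independent of the package's search code.
grid_max_oracle <- function(model, step = 0.01) {
  g <- seq(-1, 1, by = step)
  tail_grid <- as.matrix(expand.grid(B = g, C = g))
  best <- -Inf
  best_pt <- NULL
  for (a in g) {
    v <- suppressMessages(predict(model, cbind(a, tail_grid)))
    i <- which.max(v)
    if (v[i] > best) {
      best <- v[i]
      best_pt <- c(a, tail_grid[i, ])
    }
  }
  list(value = best, point = unname(best_pt))
}

# Reported reference values for the packaged Pb(II) experiment, used across
# test files.
ref_coefs <- c(94.65, 6.101, -2.180, 7.238, -11.24, -3.55, -2.84,
               -0.905, -2.401, 0.713)
ref_ypred <- c(82.88, 81.83, 94.65, 89.05, 94.03, 83.91, 84.11, 78.13,
               94.65, 96.96, 94.65, 72.49, 75.04, 64.83, 91.51)
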