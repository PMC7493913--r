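cube3 <- rbind(rep(-1, 3), rep(1, 3))

test_that("the pursuit move follows the memorized position linearly", {
  expect_equal(csa_move(0, 1, r = 0.5, fl = 2), 1)
  expect_equal(csa_move(c(0, 2), c(1, 0), r = 1, fl = 1), c(1, 0))
  expect_equal(csa_move(3, 3, r = 0.7, fl = 2), 3)  # at the memory: no move
})

test_that("config validation rejects degenerate settings", {
  expect_error(csa_config(cube3, n_crows = 1), "at least 2")
  expect_error(csa_config(cube3, fl = 0), "positive")
  expect_error(csa_config(cube3, ap = 1.2), "\\[0, 1\\]")
  expect_error(csa_config(cube3, iter_max = 0), "at least 1")
  expect_error(csa_config(rbind(1, -1)), "lower < upper")
})

test_that("with ap = 0 every update is a pursuit move toward some memory", {
  set.seed(5)
  cfg <- csa_config(rbind(rep(-10, 2), rep(10, 2)), n_crows = 6, fl = 2,
                    ap = 0, iter_max = 1, seed = 5)
  pos <- matrix(runif(12, -3, 3), ncol = 2)
  mem <- matrix(runif(12, -3, 3), ncol = 2)
  state <- list(positions = pos, memories = mem,
                mem_fit = apply(mem, 1, function(x) -sum(x^2)))
  out <- sorbRSM:::csa_step(state, function(x) -sum(x^2), cfg)
  for (i in 1:6) {
    step_vec <- out$positions[i, ] - pos[i, ]
    ok <- FALSE
    for (j in 1:6) {
      dir <- mem[j, ] - pos[i, ]
      t_hat <- if (abs(dir[1]) > 1e-12) step_vec[1] / dir[1] else NA
      if (!is.na(t_hat) && t_hat >= 0 && t_hat <= cfg$fl &&
          isTRUE(all.equal(step_vec, t_hat * dir, tolerance = 1e-8))) {
        ok <- TRUE
        break
      }
    }
    expect_true(ok, label = sprintf("crow %d moved along a memory direction", i))
  }
})

test_that("with ap = 1 every update is a uniform restart inside the bounds", {
  bounds <- rbind(c(0, -2), c(10, 2))
  cfg <- csa_config(bounds, n_crows = 40, ap = 1, iter_max = 25, seed = 9)
  seen <- new.env()
  seen$pts <- NULL
  obj <- function(x) {
    seen$pts <- rbind(seen$pts, x)
    -sum((x - c(5, 0))^2)
  }
  invisible(csa_optimize(obj, cfg))
  pts <- seen$pts[-seq_len(cfg$n_crows), , drop = FALSE]  # drop init draws
  expect_true(all(pts[, 1] >= 0 & pts[, 1] <= 10))
  expect_true(all(pts[, 2] >= -2 & pts[, 2] <= 2))
  # restarts are uniform: mean near the box midpoint (1000 draws)
  expect_equal(colMeans(pts), c(5, 0), tolerance = 0.15)
})

test_that("every evaluated position respects the bounds after clamping", {
  cfg <- csa_config(cube3, n_crows = 15, fl = 3, ap = 0.1,
                    iter_max = 40, seed = 3)
  seen <- new.env()
  seen$ok <- TRUE
  obj <- function(x) {
    if (any(x < -1 - 1e-12) || any(x > 1 + 1e-12)) seen$ok <- FALSE
    sum(x)
  }
  invisible(csa_optimize(obj, cfg))
  expect_true(seen$ok)
})

test_that("the convergence trace is monotone and ends at the best fitness", {
  cfg <- csa_config(cube3, iter_max = 80, seed = 17)
  res <- csa_optimize(function(x) -sum(x^2), cfg)
  expect_true(all(diff(res$trace) >= 0))
  expect_equal(res$best_fitness, res$trace[length(res$trace)])
  # known maximum at the origin
  expect_gt(res$best_fitness, -1e-4)
  expect_equal(res$best_position, c(0, 0, 0), tolerance = 0.05)
})

test_that("CSA matches the dense-grid oracle on a quadratic objective", {
  m <- make_surface(c(90, 0.8, -1.2, 0.5, -3, -2.5, -4, 0.6, -0.4, 0.9))
  oracle <- grid_max_oracle(m, step = 0.02)
  cfg <- csa_config(cube3, iter_max = 150, seed = 4)
  res <- csa_optimize(function(x) suppressMessages(predict(m, x)), cfg)
  expect_equal(res$best_fitness, oracle$value, tolerance = 1e-3)
})

test_that("non-finite objective values fail loudly, naming the point", {
  cfg <- csa_config(cube3, iter_max = 5, seed = 2)
  expect_error(csa_optimize(function(x) NaN, cfg), "non-finite")
})

test_that("multi-run statistics are deterministic and ordered", {
  obj <- function(x) -sum((x - 0.3)^2)
  cfg <- csa_config(cube3, iter_max = 40, seed = 21, n_runs = 6)
  a <- csa_multirun(obj, cfg)
  b <- csa_multirun(obj, cfg)
  expect_identical(a$stats, b$stats)
  expect_identical(a$run_best, b$run_best)
  expect_length(a$run_best, 6L)
  expect_gte(a$stats["best"], a$stats["mean"])
  expect_gte(a$stats["mean"], a$stats["worst"])
  expect_equal(a$best_fitness, unname(a$stats["best"]))
  expect_error(csa_multirun(obj, csa_config(cube3, n_runs = 1)), "n_runs")
})
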