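test_that("noiseless quadratic data is interpolated exactly", {
  truth <- make_surface(c(80, 3, -2, 5, -7, 1.5, -0.5, 2, -1, 0.25))
  des <- simulate_bbd_responses(truth, sigma = 0)
  fit <- fit_quadratic(des)
  expect_equal(unname(fit$model$coef), unname(truth$coef), tolerance = 1e-10)
  expect_lt(fit$model$residual_ss, 1e-16)
  expect_equal(fit$r_squared, 1)
})

test_that("refit of the packaged experiment reproduces the reported surface", {
  fit <- fit_quadratic(pb_design())
  # reported coefficients, within the rounding the 2-dp responses allow
  expect_true(all(abs(fit$model$coef - ref_coefs) < 0.005))
  # reported predicted-response column, +-0.01
  expect_true(all(abs(fit$fitted - ref_ypred) <= 0.01))
  # reported residual SS
  expect_equal(fit$model$residual_ss, 18.63, tolerance = 0.002)
  expect_equal(fit$model$residual_df, 5L)
})

test_that("predict evaluates the quadratic form at coded points", {
  m <- pb_removal_surface()
  expect_equal(predict(m, c(-1, 0, -1)), 64.83, tolerance = 1e-8)
  expect_equal(predict(m, c(0, 0, 0)), 94.65)
  expect_equal(predict(m, c(0, -1, 1)), 96.965, tolerance = 1e-8)
  # vectorized over rows
  expect_equal(predict(m, rbind(c(0, 0, 0), c(-1, 0, -1))),
               c(94.65, 64.83), tolerance = 1e-8)
  expect_message(predict(m, c(1.5, 0, 0)), "extrapolation")
})

test_that("missing responses and singular designs raise clear errors", {
  des <- bbd_design(pb_factors())
  expect_error(fit_quadratic(des), "missing responses")
  bad <- pb_design()
  bad$runs$dose <- bad$runs$pH  # C duplicates A -> collinear basis
  expect_error(fit_quadratic(bad), "singular design.*C", perl = TRUE)
})

test_that("anova satisfies the sum-of-squares decomposition identities", {
  for (des in list(pb_design(),
                   simulate_bbd_responses(sigma = 2, seed = 31))) {
    an <- rsm_anova(fit_quadratic(des))
    ss <- function(src) an$adj_ss[an$source == src]
    df <- function(src) an$df[an$source == src]
    tol <- 1e-8 * ss("Total")
    expect_equal(ss("Total"), ss("Model") + ss("Error"), tolerance = tol)
    expect_equal(ss("Error"), ss("Lack-of-Fit") + ss("Pure Error"),
                 tolerance = tol)
    # orthogonal groups are additive in members; whole model in groups
    expect_equal(ss("Linear"), ss("A") + ss("B") + ss("C"), tolerance = tol)
    expect_equal(ss("2-Way Interaction"), ss("A*B") + ss("A*C") + ss("B*C"),
                 tolerance = tol)
    expect_equal(ss("Model"),
                 ss("Linear") + ss("Square") + ss("2-Way Interaction"),
                 tolerance = tol)
    for (g in c("Model", "Linear", "Square", "2-Way Interaction", "Error")) {
      expect_equal(df(g) * an$adj_ms[an$source == g], ss(g), tolerance = tol)
    }
    expect_equal(df("Linear") + df("Square") + df("2-Way Interaction"),
                 df("Model"))
  }
})

test_that("main-effect extra SS equals the orthogonal closed form 8 beta^2", {
  fit <- fit_quadratic(pb_design())
  an <- rsm_anova(fit)
  for (term in c("A", "B", "C")) {
    expect_equal(an$adj_ss[an$source == term],
                 8 * unname(fit$model$coef[term])^2, tolerance = 1e-8)
  }
})

test_that("noiseless data yields zero error SS and infinite F ratios", {
  des <- simulate_bbd_responses(sigma = 0)
  an <- rsm_anova(fit_quadratic(des))
  expect_lt(an$adj_ss[an$source == "Error"], 1e-12)
  expect_true(is.infinite(an$f_value[an$source == "Model"]))
})

test_that("standardized effects are t statistics with t^2 = F", {
  fit <- fit_quadratic(pb_design())
  eff <- standardized_effects(fit)
  an <- rsm_anova(fit)
  for (i in seq_len(nrow(eff))) {
    expect_equal(eff$t[i]^2,
                 an$f_value[an$source == eff$term[i]], tolerance = 1e-8)
  }
  # sorted by |t| descending, threshold is the two-sided t critical value
  expect_true(all(diff(abs(eff$t)) <= 0))
  expect_equal(attr(eff, "critical"), qt(0.975, 5))
  expect_equal(eff$significant, abs(eff$t) > attr(eff, "critical"))
})

test_that("a truly null interaction is rarely flagged significant", {
  truth <- pb_removal_surface()
  truth$coef["A*B"] <- 0
  set.seed(202)
  flagged <- replicate(100, {
    des <- simulate_bbd_responses(truth, sigma = 1.93)
    eff <- standardized_effects(fit_quadratic(des), alpha = 0.05)
    eff$significant[eff$term == "A*B"]
  })
  expect_gte(mean(!flagged), 0.90)  # null term non-significant in >= 90%
})

test_that("effects_grid slices the surface consistently with predict", {
  m <- pb_removal_surface()
  # a single-point grid is just predict at that point
  g1 <- effects_grid(m, hold = "C", at = 0, step = 2)
  corner <- g1[g1$A == -1 & g1$B == -1, ]
  expect_equal(corner$predicted, predict(m, c(-1, -1, 0)))
  expect_equal(nrow(g1), 4L)  # the four corners
  # grid maximum sits at the analytic stationary point of the slice
  st <- slice_stationary(m, hold = 3, at = 0)
  g <- effects_grid(m, hold = "C", at = 0, step = 0.01)
  top <- g[which.max(g$predicted), ]
  expect_true(all(abs(c(top$A, top$B) - unname(st)) <= 0.011))
  expect_lte(max(g$predicted),
             suppressMessages(predict(m, c(st, 0)[c(1, 2, 3)])) + 1e-10)
})

test_that("quadratic models round-trip through key-value text", {
  fit <- fit_quadratic(pb_design())
  path <- withr::local_tempfile(fileext = ".txt")
  write_model(fit$model, path)
  back <- read_model(path)
  expect_equal(back$coef, fit$model$coef)
  expect_equal(back$factors, fit$model$factors)
  pts <- matrix(runif(30, -1, 1), ncol = 3)
  expect_equal(predict(back, pts), predict(fit$model, pts))
})
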