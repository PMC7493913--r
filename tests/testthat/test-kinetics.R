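# Table-scale reference conditions used across these tests: 50 mL batch,
# 75 mg adsorbent, 10 mg/L initial Pb(II).
batch <- list(c0 = 10, volume = 0.05, mass = 0.075)

test_that("removal efficiency is the percent concentration drop", {
  expect_equal(removal_efficiency(10, 0), 100)
  expect_equal(removal_efficiency(10, 10), 0)
  expect_equal(removal_efficiency(10, 0.29), 97.1)
  expect_equal(removal_efficiency(c(10, 20), c(1, 5)), c(90, 75))
  expect_error(removal_efficiency(0, 1), "positive")
  expect_error(removal_efficiency(10, -1), "non-negative")
  expect_warning(removal_efficiency(10, 12), "negative removal")
})

test_that("qt_series applies the batch mass balance", {
  tr <- kinetic_trace(c(0, 30), c(10, 4.41), c0 = 10,
                      volume = 0.05, mass = 0.075)
  qt <- qt_series(tr)
  expect_equal(qt[1], 0)
  expect_equal(qt[2], 3.727, tolerance = 1e-3)
  # linear in the concentration drop
  tr2 <- kinetic_trace(c(0, 30), c(10, 10 - 2 * (10 - 4.41)), c0 = 10,
                       volume = 0.05, mass = 0.075, tolerance = 0)
  expect_equal(qt_series(tr2)[2], 2 * qt[2])
  # removal efficiency and qt are consistent: R = 100 m qt / (V c0)
  expect_equal(removal_efficiency(tr$c0, tr$conc),
               100 * tr$mass * qt / (tr$volume * tr$c0))
})

test_that("kinetic traces validate their inputs", {
  expect_error(kinetic_trace(c(0, 5, 5), c(10, 9, 8), 10, 0.05, 0.075),
               "strictly increasing")
  expect_error(kinetic_trace(c(0, 5), c(10, 12), 10, 0.05, 0.075),
               "exceeds the initial")
  expect_error(kinetic_trace(c(0, 5), c(10, 9), 10, 0, 0.075), "positive")
  expect_error(read_trace(file.path(tempdir(), "nope.csv"), 10, 0.05, 0.075),
               "not found")
})

test_that("noiseless pseudo-first-order data is recovered to 4 significant figures", {
  qe <- 3.727; k1 <- 0.0879
  tr <- simulate_kinetic_trace("first", qe = qe, k = k1, times = seq(0, 60, 5),
                               c0 = batch$c0, volume = batch$volume,
                               mass = batch$mass)
  fit <- fit_pseudo_first_order(tr$times, qt_series(tr), qe_exp = qe)
  expect_equal(fit$qe_calc, qe, tolerance = 1e-5)
  expect_equal(fit$k1, k1, tolerance = 1e-5)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # linearization identity: slope carries -k1/ln(10)
  expect_equal(fit$slope, -fit$k1 / log(10))
})

test_that("points at or beyond the supplied plateau are excluded from the PFO fit", {
  qt <- c(0.5, 1.0, 2.0, 3.0, 3.8, 3.9)
  expect_message(
    fit <- fit_pseudo_first_order(seq_along(qt) * 10, qt, qe_exp = 3.75),
    "excluded 2")
  expect_equal(fit$n_used, 4L)
  expect_error(fit_pseudo_first_order(c(1, 2, 3), c(1, 2, 3), qe_exp = 2.5),
               "insufficient data")
})

test_that("noiseless pseudo-second-order data is recovered to 4 significant figures", {
  qe <- 3.782; k2 <- 0.1148
  tr <- simulate_kinetic_trace("second", qe = qe, k = k2,
                               times = seq(0, 120, 10),
                               c0 = batch$c0, volume = batch$volume,
                               mass = batch$mass)
  fit <- fit_pseudo_second_order(tr$times, qt_series(tr))
  expect_equal(fit$qe_calc, qe, tolerance = 1e-5)
  expect_equal(fit$k2, k2, tolerance = 1e-5)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$slope, 1 / fit$qe_calc)
})

test_that("the second-order model wins on second-order data", {
  tr <- simulate_kinetic_trace("second", qe = 3.782, k = 0.1148,
                               times = seq(0, 100, 5),
                               c0 = batch$c0, volume = batch$volume,
                               mass = batch$mass)
  qt <- qt_series(tr)
  pso <- fit_pseudo_second_order(tr$times, qt)
  pfo <- fit_pseudo_first_order(tr$times, qt, qe_exp = max(qt) * 1.001)
  expect_gt(pso$r_squared, pfo$r_squared)
})

test_that("an inapplicable second-order fit is rejected", {
  t <- c(1, 2, 4, 8)
  expect_error(fit_pseudo_second_order(t, t^2), "inapplicable")
  expect_error(fit_pseudo_second_order(c(0, 1), c(0, 1)), "insufficient data")
})

test_that("both rate laws are recovered within 10% under 1%-of-qe noise", {
  # noise sd on C_t chosen so the induced qt noise is 1% of qe; sampling
  # restricted to the pre-plateau window where the linearized PFO fit is used
  reps <- 100
  res <- list(first = matrix(NA_real_, reps, 2),
              second = matrix(NA_real_, reps, 2))
  pars <- list(first = c(qe = 3.727, k = 0.0879),
               second = c(qe = 3.782, k = 0.1148))
  set.seed(88)
  for (model in names(pars)) {
    qe <- pars[[model]]["qe"]; k <- pars[[model]]["k"]
    sig_ct <- 0.01 * qe * batch$mass / batch$volume
    for (r in seq_len(reps)) {
      tr <- simulate_kinetic_trace(model, qe = qe, k = k,
                                   times = seq(0, 40, 4), sigma = sig_ct,
                                   c0 = batch$c0, volume = batch$volume,
                                   mass = batch$mass)
      qt <- qt_series(tr)
      fit <- if (model == "first") {
        suppressMessages(fit_pseudo_first_order(tr$times, qt, qe_exp = qe))
      } else {
        fit_pseudo_second_order(tr$times, qt)
      }
      kk <- if (model == "first") fit$k1 else fit$k2
      res[[model]][r, ] <- c(abs(fit$qe_calc - qe) / qe, abs(kk - k) / k)
    }
    expect_lt(mean(res[[model]][, 1]), 0.10)  # qe relative error
    expect_lt(mean(res[[model]][, 2]), 0.10)  # rate-constant relative error
  }
})
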