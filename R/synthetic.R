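#' Factor specifications of the packaged Pb(II) biosorption experiment
#'
#' Three process factors of the batch biosorption runs: initial solution pH
#' (A, 4-8), temperature (B, 20-40 degC) and microalgal biomass dose
#' (C, 0.5-1.5 g/L), each centered at its midpoint.
#'
#' @return Named list of three [factor_spec()] objects.
#' @export
pb_factors <- function() {
  f <- list(factor_spec("pH", 4, 8),
            factor_spec("temperature", 20, 40),
            factor_spec("dose", 0.5, 1.5))
  names(f) <- vapply(f, `[[`, character(1L), "name")
  f
}

#' Packaged 15-run Pb(II) removal design table
#'
#' The Box-Behnken experiment shipped with the package: percent Pb(II)
#' removal by dried \emph{Chlorella kessleri} biomass over 15 runs (12 edge
#' points and 3 center replicates) in the factors of [pb_factors()]. Runs are
#' kept in the order of the original experiment report, which differs from
#' the canonical order [bbd_design()] emits; fits are order-invariant.
#'
#' @return A \code{design_table} with responses attached.
#' @examples
#' fit_quadratic(pb_design())
#' @export
pb_design <- function() {
  path <- system.file("extdata", "pb_bbd.csv", package = "sorbRSM",
                      mustWork = TRUE)
  read_design(path)
}

#' Reference quadratic surface for the packaged Pb(II) dataset
#'
#' The second-order coded-variable model reported for the packaged
#' experiment (response: percent Pb(II) removal):
#' \deqn{Y = 94.65 + 6.101 A - 2.180 B + 7.238 C - 11.24 A^2 - 3.55 B^2
#'       - 2.84 C^2 - 0.905 AB - 2.401 AC + 0.713 BC}
#' It serves as the default ground truth for [simulate_bbd_responses()];
#' refitting [pb_design()] reproduces these coefficients to within the
#' rounding of the recorded responses.
#'
#' @return A \code{quadratic_model}.
#' @export
pb_removal_surface <- function() {
  coefs <- c(94.65, 6.101, -2.180, 7.238, -11.24, -3.55, -2.84,
             -0.905, -2.401, 0.713)
  names(coefs) <- quad_terms(3L)
  structure(list(coef = coefs, factors = c("pH", "temperature", "dose"),
                 residual_df = 5L, residual_ss = 18.63),
            class = "quadratic_model")
}

#' Simulate responses for a Box-Behnken design from a known surface
#'
#' Emulates the data-generating process the response-surface analysis
#' assumes: the true response is a quadratic polynomial in the coded factors
#' and every run (including each center replicate, independently) is observed
#' with additive homoscedastic Gaussian noise. The center replicates'
#' independent noise is what creates pure error.
#'
#' Defaults reproduce the packaged study conditions: truth =
#' [pb_removal_surface()], noise sd \eqn{\sigma = \sqrt{3.725}} (the
#' replicate-level error variance of the packaged experiment), 3 center
#' points.
#'
#' @param truth A \code{quadratic_model} used as ground truth.
#' @param factors List of 3 [factor_spec()] (default [pb_factors()]).
#' @param sigma Noise standard deviation in response units (>= 0).
#' @param n_center Number of center replicates.
#' @param seed Integer seed, or \code{NULL} to use the current RNG state.
#' @return A \code{design_table} with simulated responses.
#' @examples
#' des <- simulate_bbd_responses(sigma = 0)
#' all.equal(fit_quadratic(des)$model$coef, coef(pb_removal_surface()))
#' @export
simulate_bbd_responses <- function(truth = pb_removal_surface(),
                                   factors = pb_factors(),
                                   sigma = sqrt(3.725),
                                   n_center = 3L, seed = NULL) {
  stopifnot(inherits(truth, "quadratic_model"), sigma >= 0)
  if (!is.null(seed)) set.seed(seed)
  des <- bbd_design(factors, n_center = n_center)
  mu <- predict(truth, coded_matrix(des))
  set_responses(des, mu + stats::rnorm(length(mu), sd = sigma))
}

#' Simulate a batch kinetic trace from a known rate law
#'
#' Generates \eqn{q_t} from the closed-form solution of the chosen rate law
#' — pseudo-first-order \eqn{q_t = q_e (1 - e^{-k_1 t})} or
#' pseudo-second-order \eqn{q_t = q_e^2 k_2 t / (1 + q_e k_2 t)} — converts
#' it to residual concentrations via the mass balance
#' \eqn{C_t = C_0 - m q_t / V}, and adds Gaussian noise on \eqn{C_t}.
#'
#' @param model \code{"second"} (default) or \code{"first"} order.
#' @param qe Equilibrium capacity (mg/g), positive.
#' @param k Rate constant (\eqn{k_1} in min\eqn{^{-1}} or \eqn{k_2} in
#'   g mg\eqn{^{-1}} min\eqn{^{-1}}), positive.
#' @param c0 Initial concentration (mg/L).
#' @param volume Solution volume (L).
#' @param mass Adsorbent mass (g).
#' @param times Sampling times (min).
#' @param sigma Noise sd on \eqn{C_t} (mg/L), default 0.
#' @param seed Integer seed, or \code{NULL}.
#' @return A \code{kinetic_trace}. Requires the mass balance to be feasible:
#'   \eqn{q_e m / V \le C_0}.
#' @examples
#' tr <- simulate_kinetic_trace("second", qe = 3.782, k = 0.1148,
#'                              c0 = 10, volume = 0.05, mass = 0.075,
#'                              times = seq(0, 120, by = 10))
#' fit_pseudo_second_order(tr$times, qt_series(tr))
#' @export
simulate_kinetic_trace <- function(model = c("second", "first"),
                                   qe, k, c0, volume, mass, times,
                                   sigma = 0, seed = NULL) {
  model <- match.arg(model)
  stopifnot(qe > 0, k > 0, c0 > 0, volume > 0, mass > 0, sigma >= 0,
            is.numeric(times))
  if (qe * mass / volume > c0 + 1e-9) {
    stop("infeasible mass balance: qe * mass / volume exceeds c0")
  }
  if (!is.null(seed)) set.seed(seed)
  qt <- switch(model,
               first = qe * (1 - exp(-k * times)),
               second = qe^2 * k * times / (1 + qe * k * times))
  conc <- c0 - mass * qt / volume + stats::rnorm(length(times), sd = sigma)
  conc <- pmax(conc, 0)
  kinetic_trace(times, conc, c0 = c0, volume = volume, mass = mass,
                tolerance = max(0.05 * c0, 6 * sigma))
}

#' The five heavy metals of the mixed-metal experiment
#'
#' @return Data frame with \code{name} and Pauling \code{electronegativity}
#'   for Pb, Cu, Co, Cd and Cr.
#' @export
heavy_metals <- function() {
  data.frame(name = c("Pb", "Cu", "Co", "Cd", "Cr"),
             electronegativity = c(2.33, 1.9, 1.88, 1.69, 1.66))
}

#' Rank metals by electronegativity
#'
#' In competitive biosorption, ions of higher electronegativity tend to bind
#' the negatively charged cell-surface groups more strongly, so descending
#' electronegativity predicts the removal-efficiency ordering (up to swaps
#' between near-equal values, such as Cu/Co here). Sorting is stable:
#' tied metals keep their input order.
#'
#' @param metals Data frame with columns \code{name} and
#'   \code{electronegativity} (positive), e.g. [heavy_metals()].
#' @return The data frame reordered by descending electronegativity.
#' @examples
#' rank_by_electronegativity(heavy_metals())$name  # "Pb" first, "Cr" last
#' @export
rank_by_electronegativity <- function(metals) {
  if (!is.data.frame(metals) || nrow(metals) == 0L) {
    stop("metals must be a non-empty data frame")
  }
  stopifnot(all(c("name", "electronegativity") %in% names(metals)))
  if (any(metals$electronegativity <= 0)) {
    stop("electronegativities must be positive")
  }
  out <- metals[order(-metals$electronegativity), , drop = FALSE]
  rownames(out) <- NULL
  out
}
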