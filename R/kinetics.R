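#' Percent removal efficiency
#'
#' \eqn{R = (C_i - C_f) / C_i \times 100}: the percentage of the initial
#' solute concentration removed from solution.
#'
#' @param c_initial Initial concentration(s), mg/L; must be positive.
#' @param c_final Final concentration(s), mg/L; must be non-negative.
#' @return Percent removal in \eqn{(-\infty, 100]}. Negative values (final
#'   above initial — desorption or inconsistent data) are returned with a
#'   warning.
#' @examples
#' removal_efficiency(10, 0.29)  # 97.1
#' @export
removal_efficiency <- function(c_initial, c_final) {
  if (any(!is.finite(c_initial)) || any(c_initial <= 0)) {
    stop("initial concentration must be positive")
  }
  if (any(!is.finite(c_final)) || any(c_final < 0)) {
    stop("final concentration must be non-negative")
  }
  r <- (c_initial - c_final) / c_initial * 100
  if (any(r < 0)) {
    warning("negative removal efficiency: final concentration exceeds initial")
  }
  r
}

#' Batch kinetic trace
#'
#' Bundles a time series of residual solute concentrations with the batch
#' constants needed to convert them to adsorbed amounts: solution volume
#' \code{V} (L), adsorbent mass \code{m} (g) and initial concentration
#' \code{c0} (mg/L).
#'
#' @param times Sampling times in minutes; non-negative, strictly increasing.
#' @param conc Residual concentrations \eqn{C_t} (mg/L), same length.
#' @param c0 Initial concentration (mg/L).
#' @param volume Solution volume (L), positive.
#' @param mass Adsorbent mass (g), positive.
#' @param tolerance Allowance above \code{c0} for measurement noise before a
#'   concentration is rejected (default 5\% of \code{c0}).
#' @return An object of class \code{kinetic_trace}.
#' @export
kinetic_trace <- function(times, conc, c0, volume, mass,
                          tolerance = 0.05 * c0) {
  stopifnot(is.numeric(times), is.numeric(conc), length(times) == length(conc))
  if (length(times) < 1L || any(times < 0) || is.unsorted(times, strictly = TRUE)) {
    stop("times must be non-negative and strictly increasing")
  }
  if (!(c0 > 0)) stop("initial concentration must be positive")
  if (!(volume > 0) || !(mass > 0)) {
    stop("volume and adsorbent mass must be positive")
  }
  if (any(conc > c0 + tolerance)) {
    stop("residual concentration exceeds the initial concentration beyond tolerance")
  }
  structure(list(times = as.numeric(times), conc = as.numeric(conc),
                 c0 = c0, volume = volume, mass = mass),
            class = "kinetic_trace")
}

#' Adsorbed amount per gram over time
#'
#' Mass balance \eqn{q_t = V (C_0 - C_t) / m}: milligrams of solute bound per
#' gram of adsorbent at each sampling time.
#'
#' @param trace A [kinetic_trace()].
#' @return Numeric vector \eqn{q_t} (mg/g), one value per time point.
#' @examples
#' tr <- kinetic_trace(c(0, 30), c(10, 4.41), c0 = 10, volume = 0.05, mass = 0.075)
#' qt_series(tr)  # 0, ~3.727
#' @export
qt_series <- function(trace) {
  stopifnot(inherits(trace, "kinetic_trace"))
  trace$volume * (trace$c0 - trace$conc) / trace$mass
}

# R^2 of a fitted straight line (computed directly so a perfect fit does not
# trip summary.lm's near-zero-variance warning).
line_r_squared <- function(linefit, y) {
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(1)
  1 - sum(stats::resid(linefit)^2) / sst
}

#' Fit the linearized pseudo-first-order kinetic model
#'
#' Lagergren model, linearized as
#' \eqn{\log_{10}(q_e - q_t) = \log_{10}(q_e) - (k_1 / \ln 10)\, t}.
#' A straight line is fitted by least squares to
#' \eqn{(t, \log_{10}(q_{e,exp} - q_t))}; then \eqn{k_1 = -\ln(10) \times}
#' slope (min\eqn{^{-1}}) and \eqn{q_{e,calc} = 10^{intercept}} (mg/g).
#' \eqn{\ln 10 = 2.302585...} is the conventional "2.303" factor. Points with
#' \eqn{q_t \ge q_{e,exp}} fall outside the domain of the logarithm; they are
#' excluded with a message reporting the count.
#'
#' @param times Sampling times (min).
#' @param qt Adsorbed amounts \eqn{q_t} (mg/g).
#' @param qe_exp Observed equilibrium capacity (mg/g), e.g. the plateau of
#'   the trace; must exceed the usable \eqn{q_t} values.
#' @return A \code{kinetic_fit}: list with \code{model = "pseudo-first-order"},
#'   \code{qe_calc}, \code{k1}, \code{r_squared}, \code{qe_exp},
#'   \code{slope}, \code{intercept}, \code{n_used}.
#' @export
fit_pseudo_first_order <- function(times, qt, qe_exp) {
  stopifnot(is.numeric(times), is.numeric(qt), length(times) == length(qt))
  if (!(qe_exp > 0)) stop("qe_exp must be positive")
  use <- is.finite(qt) & qt < qe_exp
  n_excl <- sum(!use)
  if (n_excl > 0L) {
    message("pseudo-first-order: excluded ", n_excl,
            " point(s) with qt >= qe_exp (outside the log domain)")
  }
  if (sum(use) < 3L) {
    stop("insufficient data: need at least 3 points with qt < qe_exp")
  }
  x <- times[use]
  y <- log10(qe_exp - qt[use])
  ln <- stats::lm(y ~ x)
  slope <- unname(stats::coef(ln)[2L])
  intercept <- unname(stats::coef(ln)[1L])
  structure(list(model = "pseudo-first-order",
                 qe_calc = 10^intercept,
                 k1 = -log(10) * slope,
                 r_squared = line_r_squared(ln, y),
                 qe_exp = qe_exp,
                 slope = slope, intercept = intercept,
                 n_used = sum(use)),
            class = "kinetic_fit")
}

#' Fit the linearized pseudo-second-order kinetic model
#'
#' Ho-McKay model, linearized as
#' \eqn{t / q_t = 1 / (k_2 q_e^2) + t / q_e}. A straight line is fitted by
#' least squares to \eqn{(t, t/q_t)}; then \eqn{q_{e,calc} = 1/}slope (mg/g)
#' and \eqn{k_2 = slope^2 / intercept} (g mg\eqn{^{-1}} min\eqn{^{-1}}).
#'
#' @param times Sampling times (min); points with \eqn{t \le 0} or
#'   \eqn{q_t \le 0} are excluded (the transform is undefined there).
#' @param qt Adsorbed amounts \eqn{q_t} (mg/g).
#' @return A \code{kinetic_fit} with \code{model = "pseudo-second-order"},
#'   \code{qe_calc}, \code{k2}, \code{r_squared}, \code{slope},
#'   \code{intercept}, \code{n_used}.
#' @export
fit_pseudo_second_order <- function(times, qt) {
  stopifnot(is.numeric(times), is.numeric(qt), length(times) == length(qt))
  use <- is.finite(qt) & qt > 0 & times > 0
  if (sum(use) < 3L) {
    stop("insufficient data: need at least 3 points with t > 0 and qt > 0")
  }
  x <- times[use]
  y <- x / qt[use]
  ln <- stats::lm(y ~ x)
  slope <- unname(stats::coef(ln)[2L])
  intercept <- unname(stats::coef(ln)[1L])
  if (!(slope > 0) || !(intercept > 0)) {
    stop("invalid pseudo-second-order fit: non-positive slope or intercept ",
         "(model inapplicable to these data)")
  }
  structure(list(model = "pseudo-second-order",
                 qe_calc = 1 / slope,
                 k2 = slope^2 / intercept,
                 r_squared = line_r_squared(ln, y),
                 slope = slope, intercept = intercept,
                 n_used = sum(use)),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("%s kinetic fit (n = %d)\n", x$model, x$n_used))
  rate <- if (x$model == "pseudo-first-order") {
    sprintf("k1 = %.4g min^-1", x$k1)
  } else {
    sprintf("k2 = %.4g g mg^-1 min^-1", x$k2)
  }
  cat(sprintf("  qe_calc = %.4g mg/g, %s, R^2 = %.4f\n",
              x$qe_calc, rate, x$r_squared))
  invisible(x)
}

#' Read a kinetic trace from delimited text
#'
#' Two-column comma-separated file (time, concentration) with the batch
#' constants supplied separately (typically from the pipeline config).
#'
#' @param path File path; \code{#} comment lines are ignored.
#' @param c0,volume,mass Batch constants, see [kinetic_trace()].
#' @return A \code{kinetic_trace}.
#' @export
read_trace <- function(path, c0, volume, mass) {
  if (!file.exists(path)) stop("kinetic trace file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#")
  if (ncol(df) < 2L) stop("kinetic trace needs two columns (time, concentration)")
  kinetic_trace(df[[1L]], df[[2L]], c0 = c0, volume = volume, mass = mass)
}
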