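# Canonical term labels for the full quadratic (second-order) basis in d
# factors, using the conventional design symbols A, B, C, ...
quad_terms <- function(d) {
  sym <- LETTERS[seq_len(d)]
  pairs <- utils::combn(d, 2L)
  c("(Intercept)", sym, paste0(sym, "*", sym),
    paste0(sym[pairs[1L, ]], "*", sym[pairs[2L, ]]))
}

# n x p basis matrix of the full quadratic model on coded coordinates.
quad_basis <- function(X) {
  X <- as.matrix(X)
  d <- ncol(X)
  pairs <- utils::combn(d, 2L)
  out <- cbind(1, X, X^2,
               X[, pairs[1L, ], drop = FALSE] * X[, pairs[2L, ], drop = FALSE])
  colnames(out) <- quad_terms(d)
  out
}

#' Fit the full quadratic response surface to a coded design
#'
#' Ordinary least squares of the observed response on the 10-term
#' second-order basis in the coded factors:
#' \deqn{y = \beta_0 + \sum_i \beta_i x_i + \sum_i \beta_{ii} x_i^2 +
#'       \sum_{i<j} \beta_{ij} x_i x_j + \varepsilon}
#' All fitting is done on coded coordinates; the Box-Behnken coding keeps the
#' linear and interaction columns mutually orthogonal so those effects are
#' estimated independently.
#'
#' @param design A \code{design_table} with responses attached (at least 10
#'   runs for 3 factors).
#' @return An object of class \code{rsm_fit}: list with
#'   \describe{
#'     \item{model}{a \code{quadratic_model} (named coefficient vector using
#'       the design symbols A, B, C; residual df and SS)}
#'     \item{fitted, residuals}{per-run predicted values and residuals}
#'     \item{r_squared, adj_r_squared}{\eqn{1 - SSE/SST} and its
#'       df-adjusted version}
#'     \item{design}{the input design}
#'   }
#' @examples
#' fit <- fit_quadratic(pb_design())
#' coef(fit$model)
#' @export
fit_quadratic <- function(design) {
  stopifnot(inherits(design, "design_table"))
  y <- design$runs$response
  if (anyNA(y)) stop("design has missing responses; attach them with set_responses()")
  X <- coded_matrix(design)
  p <- 1L + 2L * ncol(X) + choose(ncol(X), 2L)
  if (nrow(X) < p) {
    stop("need at least ", p, " runs to fit the full quadratic model, got ",
         nrow(X))
  }
  B <- quad_basis(X)
  qrB <- qr(B)
  if (qrB$rank < ncol(B)) {
    bad <- colnames(B)[qrB$pivot[(qrB$rank + 1L):ncol(B)]]
    stop("singular design: collinear basis columns ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm.fit(B, y)
  coefs <- fit$coefficients
  res <- fit$residuals
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  df_e <- nrow(X) - p
  model <- structure(list(
    coef = coefs,
    factors = colnames(X),
    residual_df = df_e,
    residual_ss = sse
  ), class = "quadratic_model")
  structure(list(
    model = model,
    fitted = as.numeric(B %*% coefs),
    residuals = as.numeric(res),
    r_squared = 1 - sse / sst,
    adj_r_squared = 1 - (sse / df_e) / (sst / (nrow(X) - 1L)),
    design = design
  ), class = "rsm_fit")
}

#' @export
print.rsm_fit <- function(x, ...) {
  cat("Quadratic response-surface fit\n")
  print(round(x$model$coef, 4))
  cat(sprintf("R-sq %.4f, adj R-sq %.4f, residual SS %.4f on %d df\n",
              x$r_squared, x$adj_r_squared,
              x$model$residual_ss, x$model$residual_df))
  invisible(x)
}

#' @export
coef.quadratic_model <- function(object, ...) object$coef

#' Evaluate a fitted quadratic surface at coded points
#'
#' @param object A \code{quadratic_model}.
#' @param newdata Coded coordinates: a numeric vector of length d, or a
#'   matrix / data frame with one point per row.
#' @param ... Unused.
#' @return Numeric vector of predicted responses. Points outside the coded
#'   cube \eqn{[-1,1]^d} are evaluated (the polynomial is defined everywhere)
#'   with a one-time extrapolation message.
#' @examples
#' fit <- fit_quadratic(pb_design())
#' predict(fit$model, c(0, 0, 0))      # intercept
#' predict(fit$model, rbind(c(-1, 0, -1), c(0, -1, 1)))
#' @export
predict.quadratic_model <- function(object, newdata, ...) {
  d <- length(object$factors)
  if (is.null(dim(newdata))) {
    stopifnot(length(newdata) == d)
    newdata <- matrix(as.numeric(newdata), nrow = 1L)
  }
  newdata <- as.matrix(newdata)
  stopifnot(ncol(newdata) == d)
  if (any(abs(newdata) > 1 + 1e-9)) {
    message("predict: evaluating outside the coded design cube (extrapolation)")
  }
  as.numeric(quad_basis(newdata) %*% object$coef)
}

# Residual SS of an OLS fit restricted to the basis columns `keep`.
restricted_sse <- function(B, y, keep) {
  sum(stats::lm.fit(B[, keep, drop = FALSE], y)$residuals^2)
}

#' ANOVA table for a quadratic response-surface fit
#'
#' Decomposes the total (corrected) sum of squares into model and error, the
#' model into Linear / Square / 2-Way Interaction groups and their member
#' terms, and the error into lack-of-fit and pure error. Per-term and
#' per-group "Adj SS" are extra sums of squares: the increase in residual SS
#' when that term (or whole group) is dropped from the full model. For the
#' orthogonal coded design the linear and interaction extra SS coincide with
#' sequential SS; the pure quadratic columns are not mutually orthogonal, so
#' the Square group SS is not the sum of its members' SS (both are reported,
#' as standard DoE software does).
#'
#' Pure error is the within-group SS of replicated design points (the center
#' replicates in a Box-Behnken design) about their group means. Every row's F
#' is its MS over MS(Error), except Lack-of-Fit which is tested against
#' MS(Pure Error). If there are no replicates the lack-of-fit split is
#' omitted with a message.
#'
#' @param fit An \code{rsm_fit} from [fit_quadratic()].
#' @return Data frame with columns \code{source}, \code{df}, \code{adj_ss},
#'   \code{adj_ms}, \code{f_value}, \code{p_value}. With zero residual SS the
#'   F ratios are reported as \code{Inf}.
#' @export
rsm_anova <- function(fit) {
  stopifnot(inherits(fit, "rsm_fit"))
  design <- fit$design
  y <- design$runs$response
  X <- coded_matrix(design)
  d <- ncol(X)
  B <- quad_basis(X)
  terms <- colnames(B)
  sym <- LETTERS[seq_len(d)]

  sse <- fit$model$residual_ss
  sst <- sum((y - mean(y))^2)
  ssm <- sst - sse
  df_e <- fit$model$residual_df
  mse <- if (df_e > 0) sse / df_e else NA_real_
  # a numerically exact fit has no error variance: report infinite F ratios
  if (!is.na(mse) && sst > 0 && mse < 1e-12 * sst / (length(y) - 1L)) mse <- 0

  lin_terms <- sym
  sq_terms <- paste0(sym, "*", sym)
  int_terms <- setdiff(terms, c("(Intercept)", lin_terms, sq_terms))
  groups <- list(Linear = lin_terms, Square = sq_terms,
                 `2-Way Interaction` = int_terms)

  extra_ss <- function(drop) {
    ss <- restricted_sse(B, y, setdiff(terms, drop)) - sse
    if (ss < -1e-8 * max(1, sse)) {
      stop("negative extra sum of squares for ", paste(drop, collapse = ","),
           " - numerical failure")
    }
    max(ss, 0)
  }

  rows <- list()
  add <- function(source, df, ss, f_den_ms = mse, f_den_df = df_e,
                  with_f = TRUE) {
    ms <- if (df > 0) ss / df else NA_real_
    f <- p <- NA_real_
    if (with_f && df > 0) {
      if (is.na(f_den_ms)) {
        f <- NA_real_
      } else if (f_den_ms == 0) {
        f <- Inf
        p <- 0
      } else {
        f <- ms / f_den_ms
        p <- stats::pf(f, df, f_den_df, lower.tail = FALSE)
      }
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      source = source, df = df, adj_ss = ss, adj_ms = ms,
      f_value = f, p_value = p)
  }

  add("Model", length(terms) - 1L, ssm)
  for (g in names(groups)) {
    add(g, length(groups[[g]]), extra_ss(groups[[g]]))
    for (tm in groups[[g]]) add(tm, 1L, extra_ss(tm))
  }
  add("Error", df_e, sse, with_f = FALSE)

  # replicate groups: identical coded rows
  key <- apply(X, 1L, paste, collapse = "/")
  reps <- split(y, key)
  df_pe <- length(y) - length(reps)
  if (df_pe > 0L) {
    ss_pe <- sum(vapply(reps, function(v) sum((v - mean(v))^2), numeric(1L)))
    ss_lof <- sse - ss_pe
    df_lof <- df_e - df_pe
    ms_pe <- ss_pe / df_pe
    add("Lack-of-Fit", df_lof, max(ss_lof, 0), f_den_ms = ms_pe,
        f_den_df = df_pe)
    add("Pure Error", df_pe, ss_pe, with_f = FALSE)
  } else {
    message("no replicated design points: lack-of-fit/pure-error split omitted")
  }
  add("Total", length(y) - 1L, sst, with_f = FALSE)

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Standardized effects (Pareto ranking) of the quadratic terms
#'
#' The standardized effect of a model term is its t statistic: the
#' least-squares coefficient divided by its standard error, computed from the
#' coefficient covariance \eqn{MS_E (X'X)^{-1}}. Terms are returned sorted by
#' decreasing \eqn{|t|}, the order a Pareto chart of standardized effects
#' displays. A term is flagged significant when \eqn{|t|} exceeds the
#' two-sided critical value \eqn{t_{1-\alpha/2}} with the residual degrees of
#' freedom; for any single-df term \eqn{t^2} equals its ANOVA F.
#'
#' @param fit An \code{rsm_fit}.
#' @param alpha Two-sided significance level for the threshold (default 0.05).
#' @return Data frame (sorted by \code{abs(t)} descending) with columns
#'   \code{term}, \code{estimate}, \code{se}, \code{t}, \code{p},
#'   \code{significant}; the critical value is in attribute
#'   \code{"critical"}. With zero residual variance all t are infinite and
#'   the critical value is \code{NA}.
#' @export
standardized_effects <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "rsm_fit"), alpha > 0, alpha < 1)
  df_e <- fit$model$residual_df
  if (df_e < 1L) stop("standardized effects need at least 1 residual df")
  X <- coded_matrix(fit$design)
  B <- quad_basis(X)
  mse <- fit$model$residual_ss / df_e
  xtx_inv <- chol2inv(chol(crossprod(B)))
  se <- sqrt(mse * diag(xtx_inv))
  est <- fit$model$coef
  keep <- names(est) != "(Intercept)"
  tval <- est[keep] / se[keep]
  if (mse == 0) {
    tval <- ifelse(est[keep] == 0, 0, Inf * sign(est[keep]))
    crit <- NA_real_
    pval <- rep(NA_real_, sum(keep))
  } else {
    crit <- stats::qt(1 - alpha / 2, df_e)
    pval <- 2 * stats::pt(abs(tval), df_e, lower.tail = FALSE)
  }
  out <- data.frame(term = names(est)[keep], estimate = est[keep],
                    se = se[keep], t = tval, p = pval,
                    significant = is.na(crit) | abs(tval) > crit)
  out <- out[order(-abs(out$t)), ]
  rownames(out) <- NULL
  attr(out, "critical") <- crit
  attr(out, "alpha") <- alpha
  out
}

#' Prediction grid over two factors with the third held fixed
#'
#' Evaluates the fitted surface on a rectangular coded grid over two factors
#' while the remaining factor is held at a fixed coded value — the numeric
#' table behind a response-surface or contour plot.
#'
#' @param model A \code{quadratic_model}.
#' @param hold Symbol (\code{"A"}, \code{"B"}, \code{"C"}) or index of the
#'   factor to hold fixed.
#' @param at Coded value for the held factor (default 0, the center point).
#' @param step Grid spacing over \eqn{[-1, 1]} for the varying factors.
#' @return Long-format data frame: one row per grid cell with the two varying
#'   symbols and \code{predicted}.
#' @export
effects_grid <- function(model, hold, at = 0, step = 0.05) {
  stopifnot(inherits(model, "quadratic_model"))
  d <- length(model$factors)
  sym <- LETTERS[seq_len(d)]
  if (is.character(hold)) hold <- match(hold, sym)
  if (is.na(hold) || hold < 1L || hold > d) stop("unknown factor to hold")
  vary <- setdiff(seq_len(d), hold)
  g <- seq(-1, 1, by = step)
  grid <- expand.grid(v1 = g, v2 = g)
  pts <- matrix(at, nrow = nrow(grid), ncol = d)
  pts[, vary[1L]] <- grid$v1
  pts[, vary[2L]] <- grid$v2
  out <- data.frame(grid$v1, grid$v2,
                    predicted = predict(model, pts))
  names(out)[1:2] <- sym[vary]
  out
}

#' Serialize a quadratic model as flat key-value text
#'
#' One \code{term=value} line per coefficient at full precision, plus the
#' factor names and residual df/SS, so downstream optimization steps can
#' reload the surface without the original data.
#'
#' @param model A \code{quadratic_model}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "quadratic_model"))
  kv <- c(sprintf("factors=%s", paste(model$factors, collapse = ",")),
          sprintf("residual_df=%d", model$residual_df),
          sprintf("residual_ss=%.17g", model$residual_ss),
          sprintf("%s=%.17g", names(model$coef), model$coef))
  writeLines(kv, path)
  invisible(path)
}

#' Read a quadratic model written by [write_model()]
#'
#' @param path File path.
#' @return A \code{quadratic_model}.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  kv <- read_kv(path)
  factors <- strsplit(kv[["factors"]], ",")[[1L]]
  terms <- quad_terms(length(factors))
  coefs <- vapply(terms, function(t) as.numeric(kv[[t]]), numeric(1L))
  names(coefs) <- terms
  structure(list(coef = coefs, factors = factors,
                 residual_df = as.integer(kv[["residual_df"]]),
                 residual_ss = as.numeric(kv[["residual_ss"]])),
            class = "quadratic_model")
}
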