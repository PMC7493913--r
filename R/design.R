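#' Define an experimental factor
#'
#' A factor specification records the actual-unit range over which a process
#' variable is varied in a designed experiment, together with its center
#' point. Coded levels -1, 0 and +1 map onto \code{low}, \code{center} and
#' \code{high}. The center must sit exactly halfway between the range ends,
#' so that the coding transform \code{coded = (actual - center) / half_range}
#' is well defined.
#'
#' @param name Character label for the factor (e.g. \code{"pH"}).
#' @param low,high Actual-unit range ends; \code{low < high}.
#' @param center Actual-unit center point; defaults to the midpoint and must
#'   equal \code{(low + high) / 2}.
#' @return An object of class \code{factor_spec}.
#' @examples
#' factor_spec("pH", 4, 8)
#' @export
factor_spec <- function(name, low, high, center = (low + high) / 2) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(low) || !is.numeric(high) || !is.numeric(center) ||
      anyNA(c(low, high, center))) {
    stop("factor '", name, "': low, high and center must be finite numbers")
  }
  if (!(low < center && center < high)) {
    stop("factor '", name, "': requires low < center < high (got ",
         low, ", ", center, ", ", high, ")")
  }
  mid <- (low + high) / 2
  if (abs(center - mid) > 1e-8 * max(1, abs(mid))) {
    stop("factor '", name, "': center (", center,
         ") must equal the range midpoint (", mid,
         ") for the linear coding transform")
  }
  structure(list(name = name, low = low, high = high, center = center),
            class = "factor_spec")
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("factor %s: levels -1/0/+1 = %g / %g / %g\n",
              x$name, x$low, x$center, x$high))
  invisible(x)
}

#' Decode a coded factor level to actual units
#'
#' The affine coding transform maps the factor range onto \eqn{[-1, +1]}:
#' \eqn{actual = center + coded \times (high - low) / 2}. Values outside
#' \eqn{[-1, 1]} are decoded as well (linear extrapolation beyond the design
#' region).
#'
#' @param spec A [factor_spec()].
#' @param coded Numeric vector of coded levels.
#' @return Actual-unit values, same length as \code{coded}.
#' @seealso [to_coded()]
#' @examples
#' to_actual(factor_spec("pH", 4, 8), c(-1, 0, 0.1717, 1))
#' @export
to_actual <- function(spec, coded) {
  stopifnot(inherits(spec, "factor_spec"), is.numeric(coded))
  spec$center + coded * (spec$high - spec$low) / 2
}

#' Code an actual factor value
#'
#' Exact inverse of [to_actual()]:
#' \eqn{coded = (actual - center) / ((high - low)/2)}, i.e. the deviation
#' from the center divided by the half-range.
#'
#' @param spec A [factor_spec()].
#' @param actual Numeric vector in actual units.
#' @return Coded values; \code{low} maps to -1 and \code{high} to +1 exactly.
#' @export
to_coded <- function(spec, actual) {
  stopifnot(inherits(spec, "factor_spec"), is.numeric(actual))
  (actual - spec$center) / ((spec$high - spec$low) / 2)
}

# 12 edge midpoints of the cube for a 3-factor Box-Behnken design, in the
# canonical block order (pairs (1,2), (1,3), (2,3); within a block the
# off-zero coordinates run (-1,-1), (-1,+1), (+1,-1), (+1,+1)).
bbd_edge_points <- function() {
  signs <- as.matrix(expand.grid(s2 = c(-1, 1), s1 = c(-1, 1)))[, c("s1", "s2")]
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  out <- matrix(0, nrow = 12L, ncol = 3L)
  row <- 1L
  for (p in pairs) {
    for (k in seq_len(4L)) {
      out[row, p] <- signs[k, ]
      row <- row + 1L
    }
  }
  out
}

#' Construct a three-factor Box-Behnken design
#'
#' Builds the 12 edge midpoints of the \eqn{[-1,1]^3} cube
#' (\eqn{(\pm1,\pm1,0)}, \eqn{(\pm1,0,\pm1)}, \eqn{(0,\pm1,\pm1)}) followed by
#' \code{n_center} replicated center runs \eqn{(0,0,0)}. Every coded level is
#' in \{-1, 0, +1\}; the coded columns are mean-zero and pairwise orthogonal,
#' and each factor is at \eqn{\pm1} in exactly 8 runs. Center replicates are
#' what provide the pure-error estimate in [rsm_anova()].
#'
#' Edge runs are emitted in a fixed lexicographic block order (factor pairs
#' (1,2), (1,3), (2,3); signs (-,-), (-,+), (+,-), (+,+) within a block) and
#' run ids are \code{1:(12 + n_center)}. Model fits are invariant to run
#' order.
#'
#' @param factors List of exactly 3 [factor_spec()] objects.
#' @param n_center Number of center-point replicates (default 3).
#' @param responses Optional numeric vector of observed responses (percent
#'   removal, one per run) to attach.
#' @return A \code{design_table}: list with \code{factors} and a \code{runs}
#'   data frame holding run id, coded levels (columns named after the
#'   factors), actual levels (suffix \code{_actual}) and \code{response}.
#' @examples
#' des <- bbd_design(list(
#'   factor_spec("pH", 4, 8),
#'   factor_spec("temperature", 20, 40),
#'   factor_spec("dose", 0.5, 1.5)
#' ))
#' nrow(des$runs)  # 15
#' @export
bbd_design <- function(factors, n_center = 3L, responses = NULL) {
  if (!is.list(factors) || length(factors) != 3L) {
    stop("unsupported design: exactly 3 factors are required (got ",
         length(factors), ")")
  }
  for (f in factors) {
    if (!inherits(f, "factor_spec")) stop("factors must be factor_spec objects")
  }
  nm <- vapply(factors, `[[`, character(1L), "name")
  if (anyDuplicated(nm)) stop("factor names must be unique")
  n_center <- as.integer(n_center)
  if (is.na(n_center) || n_center < 1L) stop("n_center must be at least 1")

  coded <- rbind(bbd_edge_points(),
                 matrix(0, nrow = n_center, ncol = 3L))
  colnames(coded) <- nm
  runs <- data.frame(run = seq_len(nrow(coded)))
  runs[nm] <- as.data.frame(coded)
  for (i in seq_along(factors)) {
    runs[[paste0(nm[i], "_actual")]] <- to_actual(factors[[i]], coded[, i])
  }
  runs$response <- NA_real_
  names(factors) <- nm
  des <- structure(list(factors = factors, runs = runs),
                   class = "design_table")
  if (!is.null(responses)) des <- set_responses(des, responses)
  des
}

#' Attach observed responses to a design
#'
#' @param design A \code{design_table}.
#' @param responses Numeric vector, one percent-removal value per run.
#' @return The design with its \code{response} column filled.
#' @export
set_responses <- function(design, responses) {
  stopifnot(inherits(design, "design_table"))
  if (!is.numeric(responses) || length(responses) != nrow(design$runs)) {
    stop("responses must be numeric with one value per run (",
         nrow(design$runs), " expected, got ", length(responses), ")")
  }
  if (anyNA(responses)) stop("responses must not contain missing values")
  design$runs$response <- as.numeric(responses)
  design
}

#' Coded design matrix of a design table
#'
#' @param design A \code{design_table}.
#' @return Numeric matrix (runs x factors) of coded levels.
#' @export
coded_matrix <- function(design) {
  stopifnot(inherits(design, "design_table"))
  as.matrix(design$runs[names(design$factors)])
}

#' @export
print.design_table <- function(x, ...) {
  cat(sprintf("Box-Behnken design: %d factors, %d runs (%d with responses)\n",
              length(x$factors), nrow(x$runs), sum(!is.na(x$runs$response))))
  print(x$runs, row.names = FALSE)
  invisible(x)
}

#' Write a design table as delimited text
#'
#' Comma-separated with one header row (run, coded columns, actual columns,
#' response) plus leading \code{#} comment lines carrying the factor ranges
#' (and optionally a seed), so the file round-trips through [read_design()].
#'
#' @param design A \code{design_table}.
#' @param path Output file path.
#' @param seed Optional integer recorded in the header comment.
#' @return \code{path}, invisibly.
#' @export
write_design <- function(design, path, seed = NULL) {
  stopifnot(inherits(design, "design_table"))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in design$factors) {
    writeLines(sprintf("# factor: %s,%.10g,%.10g", f$name, f$low, f$high), con)
  }
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  utils::write.csv(design$runs, con, row.names = FALSE)
  invisible(path)
}

#' Read a design table written by [write_design()]
#'
#' @param path File path. Factor ranges are recovered from the \code{# factor:}
#'   header comments; if absent, \code{factors} must be supplied.
#' @param factors Optional list of [factor_spec()] overriding the header.
#' @return A \code{design_table}.
#' @export
read_design <- function(path, factors = NULL) {
  if (!file.exists(path)) stop("design file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  if (is.null(factors)) {
    fl <- sub("^# factor: ", "", grep("^# factor: ", hdr, value = TRUE))
    if (length(fl) == 0L) stop("no '# factor:' header in ", path,
                               " and no factors supplied")
    factors <- lapply(strsplit(fl, ","), function(p) {
      factor_spec(p[1L], as.numeric(p[2L]), as.numeric(p[3L]))
    })
  }
  runs <- utils::read.csv(textConnection(grep("^#", lines,
                                              invert = TRUE, value = TRUE)))
  nm <- vapply(factors, `[[`, character(1L), "name")
  missing_cols <- setdiff(c("run", nm, "response"), names(runs))
  if (length(missing_cols) > 0L) {
    stop("design file ", path, " lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  names(factors) <- nm
  structure(list(factors = factors, runs = runs), class = "design_table")
}
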