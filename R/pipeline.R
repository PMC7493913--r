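#' Read a flat key-value text file
#'
#' One \code{key=value} pair per line; blank lines and \code{#} comments are
#' ignored. Values are returned as character strings.
#'
#' @param path File path.
#' @return Named list of character values.
#' @export
read_kv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  eq <- regexpr("=", lines, fixed = TRUE)
  if (any(eq < 0L)) stop("malformed key-value line in ", path)
  keys <- substr(lines, 1L, eq - 1L)
  vals <- substr(lines, eq + 1L, nchar(lines))
  stats::setNames(as.list(trimws(vals)), trimws(keys))
}

#' Write a flat key-value text file
#'
#' @param x Named list or vector of scalar values.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_kv <- function(x, path) {
  stopifnot(!is.null(names(x)), all(nzchar(names(x))))
  vals <- vapply(x, function(v) {
    if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
  }, character(1L))
  writeLines(paste0(names(x), "=", vals), path)
  invisible(path)
}

# Default pipeline settings; overridden by entries of a config list/file.
default_config <- function() {
  list(
    design_file = system.file("extdata", "pb_bbd.csv", package = "sorbRSM"),
    lower = NA_real_,   # desirability L; NA = min observed response
    upper = 100,        # ceiling of a percent-removal response
    weight = 1,
    grid_step = 0.01,
    n_crows = 50L, fl = 2, ap = 0.1, iter_max = 150L, n_runs = 50L,
    seed = 0L,
    alpha = 0.05,
    kinetics_file = NULL, c0 = NA_real_, volume = NA_real_, mass = NA_real_,
    qe_exp = NA_real_
  )
}

#' Read a pipeline configuration file
#'
#' Flat \code{key=value} text accepting the fields of the pipeline defaults
#' (design_file, lower, upper, weight, grid_step, n_crows, fl, ap, iter_max,
#' n_runs, seed, alpha, kinetics_file, c0, volume, mass, qe_exp). Unknown
#' keys are rejected.
#'
#' @param path Config file path.
#' @return Config list, usable as \code{config} in [run_pipeline()].
#' @export
read_config <- function(path) {
  kv <- read_kv(path)
  def <- default_config()
  unknown <- setdiff(names(kv), names(def))
  if (length(unknown) > 0L) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  num <- c("lower", "upper", "weight", "grid_step", "fl", "ap",
           "c0", "volume", "mass", "qe_exp", "alpha")
  int <- c("n_crows", "iter_max", "n_runs", "seed")
  for (k in names(kv)) {
    def[[k]] <- if (k %in% num) as.numeric(kv[[k]])
                else if (k %in% int) as.integer(kv[[k]])
                else kv[[k]]
  }
  def
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full optimization pipeline
#'
#' Executes the whole analysis over a design/response table: quadratic
#' response-surface fit, ANOVA with lack-of-fit split, standardized-effect
#' ranking, desirability optimization over the coded cube, crow-search
#' optimization of the same fitted surface with multi-run spread statistics,
#' and (if a kinetics file is configured) linearized pseudo-first/second-order
#' kinetic fits. Every stage's table is written under \code{out_dir} as
#' delimited or key-value text, and a log line records the package version,
#' seed and config hash. All randomness derives from \code{config$seed}, so
#' repeated runs produce identical machine-readable outputs.
#'
#' @param config Config list (see [read_config()]) or path to a config file.
#'   Omitted entries fall back to the packaged defaults, which analyse the
#'   packaged Pb(II) design.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress log messages.
#' @return Invisibly, a list with elements \code{fit}, \code{anova},
#'   \code{effects}, \code{df_optimum}, \code{csa}, and (when configured)
#'   \code{kinetics}, plus \code{files} naming everything written.
#' @export
run_pipeline <- function(config = list(), out_dir = "results",
                         quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  cfg <- utils::modifyList(default_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- function(...) if (!quiet) message("[pipeline] ", sprintf(...))

  cfg_file <- tempfile(fileext = ".conf")
  write_kv(Filter(Negate(is.null), cfg), cfg_file)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)
  log("sorbRSM %s, seed %d, config %s",
      as.character(utils::packageVersion("sorbRSM")), cfg$seed, cfg_hash)

  design <- run_stage("load-design", {
    if (!file.exists(cfg$design_file)) {
      stop("design/response file not found: ", cfg$design_file)
    }
    read_design(cfg$design_file)
  })
  log("loaded %d runs from %s", nrow(design$runs), cfg$design_file)

  fit <- run_stage("fit", fit_quadratic(design))
  log("fitted quadratic surface: R-sq %.4f", fit$r_squared)
  an <- run_stage("anova", rsm_anova(fit))
  eff <- run_stage("effects", standardized_effects(fit, alpha = cfg$alpha))

  lower <- if (is.na(cfg$lower)) min(design$runs$response) else cfg$lower
  log("desirability bounds: L = %.4g (%s), U = %.4g, w = %g",
      lower, if (is.na(cfg$lower)) "min observed response" else "config",
      cfg$upper, cfg$weight)
  opt_df <- run_stage("optimize-df", maximize_desirability(
    fit$model, lower = lower, upper = cfg$upper, weight = cfg$weight,
    grid_step = cfg$grid_step, factors = design$factors))
  log("desirability optimum: predicted %.4f, D = %.4f",
      opt_df$predicted, opt_df$D)

  csa_cfg <- csa_config(rbind(rep(-1, 3), rep(1, 3)),
                        n_crows = cfg$n_crows, fl = cfg$fl, ap = cfg$ap,
                        iter_max = cfg$iter_max, seed = cfg$seed,
                        n_runs = cfg$n_runs)
  objective <- function(x) predict_quiet(fit$model, x)
  csa_res <- run_stage("optimize-csa", {
    if (cfg$n_runs >= 2L) csa_multirun(objective, csa_cfg)
    else csa_optimize(objective, csa_cfg)
  })
  log("CSA best fitness %.6f (seed %d, %d run(s))",
      csa_res$best_fitness, cfg$seed, cfg$n_runs)

  kin <- NULL
  if (!is.null(cfg$kinetics_file) && nzchar(cfg$kinetics_file)) {
    kin <- run_stage("kinetics", {
      tr <- read_trace(cfg$kinetics_file, c0 = cfg$c0,
                       volume = cfg$volume, mass = cfg$mass)
      qt <- qt_series(tr)
      qe_exp <- if (is.na(cfg$qe_exp)) {
        log("qe_exp not configured: using the final observed qt (%.4g mg/g)",
            qt[length(qt)])
        qt[length(qt)]
      } else cfg$qe_exp
      list(trace = tr,
           first = fit_pseudo_first_order(tr$times, qt, qe_exp),
           second = fit_pseudo_second_order(tr$times, qt))
    })
  }

  files <- c(
    model = write_model(fit$model, file.path(out_dir, "model.txt")),
    anova = {
      utils::write.csv(an, file.path(out_dir, "anova.csv"), row.names = FALSE)
      file.path(out_dir, "anova.csv")
    },
    effects = {
      utils::write.csv(eff, file.path(out_dir, "effects.csv"),
                       row.names = FALSE)
      file.path(out_dir, "effects.csv")
    },
    df_optimum = write_optimum(opt_df, file.path(out_dir, "optimum_df.txt")),
    csa_trace = write_trace(csa_res, file.path(out_dir, "csa_trace.csv")),
    csa_summary = {
      coords <- stats::setNames(as.list(csa_res$best_position),
                                paste0("coded_", fit$model$factors))
      s <- c(coords, list(best_fitness = csa_res$best_fitness))
      if (!is.null(csa_res$stats)) s <- c(s, as.list(csa_res$stats))
      write_kv(s, file.path(out_dir, "csa_summary.txt"))
      file.path(out_dir, "csa_summary.txt")
    }
  )
  if (!is.null(kin)) {
    kin_kv <- list(
      qe_exp = kin$first$qe_exp,
      pfo_qe_calc = kin$first$qe_calc, pfo_k1 = kin$first$k1,
      pfo_r_squared = kin$first$r_squared,
      pso_qe_calc = kin$second$qe_calc, pso_k2 = kin$second$k2,
      pso_r_squared = kin$second$r_squared)
    files["kinetics"] <- write_kv(kin_kv, file.path(out_dir, "kinetics.txt"))
  }
  log("wrote %d output files to %s", length(files), out_dir)

  invisible(list(fit = fit, anova = an, effects = eff, df_optimum = opt_df,
                 csa = csa_res, kinetics = kin, files = files))
}
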