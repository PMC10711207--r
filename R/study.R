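#' Configuration of a full uncertainty study
#'
#' Bundles the uncertain-input table, the polynomial chaos settings, the
#' waveform and solver parameters and the output directory. The defaults
#' reproduce the study design: the seven uniform inputs, hyperemic FFR as
#' the output at `(p = 3, nps = 2)`, a 1.0 s cycle with 120 timesteps, a
#' fixed 35% eccentricity, and microvascular resistance calibrated to a
#' 1 ml/s baseline mean flow at input means.
#'
#' @param condition `"hyperemia"` (FFR study) or `"baseline"` (proximal
#'   WSS study).
#' @param p Total polynomial order.
#' @param nps Oversampling ratio `Ns / Np`.
#' @param seed Integer seed for the Latin hypercube design.
#' @param vars List of [uncertain_variable()]s.
#' @param eps0 Fixed stenosis eccentricity fraction.
#' @param L_in,L_out Straight inlet/outlet conduit lengths, mm.
#' @param target_mean_Q Baseline calibration flow target, ml/s.
#' @param period,n_steps Cardiac cycle duration (s) and timesteps per cycle.
#' @param Kt Expansion-loss constant of the reduced solver.
#' @param Pv Venous pressure, mmHg.
#' @param hyperemia_factor Resistance multiplier under hyperemia.
#' @param n_resample Resample size for density/interval estimation.
#' @param out_dir Output directory for artifacts, or `NULL` to skip writing.
#' @return Object of class `study_config`.
#' @export
study_config <- function(condition = c("hyperemia", "baseline"),
                         p = 3, nps = 2, seed = 1,
                         vars = default_study_inputs(),
                         eps0 = 0.35, L_in = 10, L_out = 25,
                         target_mean_Q = 1.0, period = 1.0, n_steps = 120,
                         Kt = 1.52, Pv = 0, hyperemia_factor = 0.25,
                         n_resample = 1e5, out_dir = NULL) {
  condition <- match.arg(condition)
  structure(list(version = "1", condition = condition, p = p, nps = nps,
                 seed = as.integer(seed), vars = vars, eps0 = eps0,
                 L_in = L_in, L_out = L_out, target_mean_Q = target_mean_Q,
                 period = period, n_steps = as.integer(n_steps), Kt = Kt,
                 Pv = Pv, hyperemia_factor = hyperemia_factor,
                 n_resample = n_resample, out_dir = out_dir),
            class = "study_config")
}

#' Read/write a study configuration as YAML
#'
#' The YAML round trip is loss-free: `read_study_config(write_study_config(x))`
#' reproduces `x`.
#'
#' @param config A [study_config()].
#' @param path YAML file path.
#' @export
write_study_config <- function(config, path) {
  lst <- unclass(config)
  lst$vars <- lapply(config$vars, function(v) {
    list(name = v$name, mean = v$mean,
         rel_uncertainty = if (is.null(v$rel_uncertainty)) NA
                           else v$rel_uncertainty,
         lower = v$lower, upper = v$upper)
  })
  lst$out_dir <- if (is.null(config$out_dir)) NA else config$out_dir
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  lst <- yaml::read_yaml(path)
  vars <- lapply(lst$vars, function(v) {
    out <- uncertain_variable(v$name, lower = v$lower, upper = v$upper)
    out$mean <- v$mean
    if (!is.na(v$rel_uncertainty)) out$rel_uncertainty <- v$rel_uncertainty
    out
  })
  study_config(condition = lst$condition, p = lst$p, nps = lst$nps,
               seed = lst$seed, vars = vars, eps0 = lst$eps0,
               L_in = lst$L_in, L_out = lst$L_out,
               target_mean_Q = lst$target_mean_Q, period = lst$period,
               n_steps = lst$n_steps, Kt = lst$Kt, Pv = lst$Pv,
               hyperemia_factor = lst$hyperemia_factor,
               n_resample = lst$n_resample,
               out_dir = if (is.na(lst$out_dir)) NULL else lst$out_dir)
}

# Geometry at a named input vector (x has entries Li, Lm, Lo, D, s0).
geometry_from_inputs <- function(x, config) {
  stenosis_geometry(Li = x[["Li"]], Lm = x[["Lm"]], Lo = x[["Lo"]],
                    D = x[["D"]], s0 = x[["s0"]], eps0 = config$eps0,
                    L_in = config$L_in, L_out = config$L_out)
}

# Calibrate R_micro_base once at the input means of the configuration.
calibrate_at_means <- function(config, blood = blood_properties()) {
  mu <- var_means(config$vars)
  geom <- geometry_from_inputs(mu, config)
  wf <- make_waveform(mu[["Pa"]], period = config$period,
                      n_steps = config$n_steps)
  calibrate_rmicro(geom, blood, wf, target_mean_Q = config$target_mean_Q,
                   Kt = config$Kt, Pv = config$Pv)
}

# Closure mapping a named input vector to the study output (FFR or AWSS).
study_model_runner <- function(config, R_micro_base,
                               blood = blood_properties()) {
  force(R_micro_base)
  function(x) {
    geom <- geometry_from_inputs(x, config)
    wf <- make_waveform(x[["Pa"]], period = config$period,
                        n_steps = config$n_steps)
    lpn <- lpn_params(R_micro_base = R_micro_base,
                      hyperemia_factor = config$hyperemia_factor,
                      R_multiplier = x[["R"]], Pv = config$Pv)
    res <- transient_solve(geom, blood, lpn, wf,
                           condition = config$condition, Kt = config$Kt)
    if (config$condition == "hyperemia") res$FFR else res$AWSS_prox
  }
}

#' Run a full uncertainty study
#'
#' Executes the pipeline: microvascular calibration at input means, seeded
#' Latin hypercube design, one reduced-order transient solve per sample
#' (FFR under hyperemia or average proximal WSS at baseline), least-squares
#' PCE fit and UQ/SA report. When `config$out_dir` is set, writes
#' `design.csv`, `samples.csv` (inputs, output, ok flag), `surrogate.json`,
#' `report.json` and `sensitivity.csv`.
#'
#' @param config A [study_config()].
#' @param quiet Suppress per-stage log messages?
#' @return The [uq_report()], with attributes `design`, `outputs`,
#'   `surrogate`, `R_micro_base` and `output_name`.
#' @export
run_study <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "study_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  output_name <- if (config$condition == "hyperemia") "FFR" else "AWSS_prox_Pa"
  blood <- blood_properties()

  say("[calibrate] matching %.3g ml/s baseline mean flow at input means",
      config$target_mean_Q)
  R_micro_base <- calibrate_at_means(config, blood)
  say("[calibrate] R_micro_base = %.6g mmHg s/ml", R_micro_base)

  n <- length(config$vars)
  iset <- build_index_set(n, config$p)
  Ns <- required_samples(iset$Np, config$nps)
  say("[design] n = %d, p = %d, Np = %d, nps = %g, Ns = %d, seed = %d",
      n, config$p, iset$Np, config$nps, Ns, config$seed)
  design <- lhs_sample(config$vars, Ns, config$seed)

  runner <- study_model_runner(config, R_micro_base, blood)
  say("[solve] %d transient solves, condition = %s", Ns, config$condition)
  y <- apply(design$values, 1L, function(x) {
    tryCatch(runner(x), error = function(e) NA_real_)
  })
  ok <- !is.na(y)
  if (any(!ok)) say("[solve] %d of %d runs failed", sum(!ok), Ns)
  if (sum(ok) < iset$Np)
    stop(sprintf("[solve] only %d successful runs for Np = %d terms",
                 sum(ok), iset$Np))
  fit_design <- design
  if (any(!ok)) {
    fit_design$unit_coords <- design$unit_coords[ok, , drop = FALSE]
    fit_design$values <- design$values[ok, , drop = FALSE]
    fit_design$Ns <- sum(ok)
  }
  say("[fit] least-squares PCE, %d terms", iset$Np)
  s <- fit_pce(fit_design, y[ok], iset)
  say("[fit] cond(Psi) = %.3g, residual norm = %.3g",
      s$condition_number, s$residual_norm)

  say("[uqsa] moments, Sobol indices, density (%d resamples)",
      as.integer(config$n_resample))
  report <- uq_report(s, n_resample = config$n_resample,
                      seed = config$seed + 1L)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(f) file.path(config$out_dir, f)
    write_design(design, fp("design.csv"))
    samples <- cbind(as.data.frame(design),
                     output = y, ok = ok)
    names(samples)[names(samples) == "output"] <- output_name
    utils::write.csv(samples, fp("samples.csv"), row.names = FALSE)
    write_surrogate(s, fp("surrogate.json"))
    write_report_json(report, output_name, config, fp("report.json"))
    sensitivity_table(report, fp("sensitivity.csv"))
    say("[write] artifacts in %s", config$out_dir)
  }
  attr(report, "design") <- design
  attr(report, "outputs") <- y
  attr(report, "surrogate") <- s
  attr(report, "R_micro_base") <- R_micro_base
  attr(report, "output_name") <- output_name
  report
}

write_report_json <- function(report, output_name, config, path) {
  jsonlite::write_json(list(
    output = output_name, condition = config$condition,
    p = config$p, nps = config$nps, seed = config$seed,
    Np = report$Np, Ns = report$Ns,
    mean = report$mean, variance = report$variance, std = report$std,
    skewness = report$skewness,
    pi95 = report$pi95,
    Si = as.list(report$Si), SiT = as.list(report$SiT)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the (p, nps) convergence grid for a study
#'
#' Delegates to [convergence_study()] with the study's model runner
#' (calibration done once at input means) and optionally writes the grid
#' to `convergence.csv` in the configured output directory.
#'
#' @param config A [study_config()].
#' @param p_list,nps_list Grid of polynomial orders and oversampling ratios.
#' @param quiet Suppress log messages?
#' @return The convergence table (see [convergence_study()]).
#' @export
run_convergence <- function(config, p_list = 1:4, nps_list = c(1, 2),
                            quiet = FALSE) {
  stopifnot(inherits(config, "study_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  blood <- blood_properties()
  R_micro_base <- calibrate_at_means(config, blood)
  runner <- study_model_runner(config, R_micro_base, blood)
  say("[convergence] grid of %d cells, condition = %s",
      length(p_list) * length(nps_list), config$condition)
  tab <- convergence_study(runner, config$vars, p_list = p_list,
                           nps_list = nps_list, seed = config$seed)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(config$out_dir, "convergence.csv"),
                     row.names = FALSE)
  }
  tab
}
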