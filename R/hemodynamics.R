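# Unit conventions: lengths mm, pressures mmHg, flow ml/s, shear Pa.
# Internal conversions to SI use these constants.
PA_PER_MMHG <- 133.322387415
# Pa*s/m^3 -> mmHg*s/ml
RES_SI_TO_CLIN <- 1e-6 / PA_PER_MMHG

#' Blood rheological properties
#'
#' @param density Blood density, kg/m^3.
#' @param kinematic_viscosity Kinematic viscosity, m^2/s.
#' @return Object of class `blood_properties` with the derived dynamic
#'   viscosity `mu = density * kinematic_viscosity` in Pa s.
#' @export
blood_properties <- function(density = 1050, kinematic_viscosity = 3.5e-6) {
  if (density <= 0 || kinematic_viscosity <= 0)
    stop("blood properties must be positive")
  structure(list(density = density,
                 kinematic_viscosity = kinematic_viscosity,
                 mu = density * kinematic_viscosity),
            class = "blood_properties")
}

#' Lumped-parameter outlet (coronary microcirculation) parameters
#'
#' @param R_micro_base Calibrated baseline microcirculation resistance,
#'   mmHg s/ml (see [calibrate_rmicro()]).
#' @param hyperemia_factor Multiplier applied to the microvascular resistance
#'   under hyperemia; 0.25 models maximal vasodilation (resistance quartered).
#' @param R_multiplier Sampled normalized resistance (the uncertain input
#'   `R`), multiplying `R_micro_base` in both conditions.
#' @param Pv Venous (outflow reference) pressure, mmHg.
#' @param C Optional microcirculation compliance, ml/mmHg; 0 gives the
#'   default quasi-steady resistive network.
#' @return Object of class `lpn_params`.
#' @export
lpn_params <- function(R_micro_base, hyperemia_factor = 0.25,
                       R_multiplier = 1, Pv = 0, C = 0) {
  if (R_micro_base <= 0) stop("R_micro_base must be positive")
  if (R_multiplier <= 0) stop("R_multiplier must be positive")
  if (C < 0) stop("compliance must be nonnegative")
  structure(list(R_micro_base = R_micro_base,
                 hyperemia_factor = hyperemia_factor,
                 R_multiplier = R_multiplier, Pv = Pv, C = C),
            class = "lpn_params")
}

#' Aortic inlet pressure waveform
#'
#' A smooth periodic two-harmonic stand-in for a physiological aortic
#' pressure trace (systolic rise, diastolic decay), discretized at `n_steps`
#' per cycle and rescaled multiplicatively so that the arithmetic mean of
#' the samples equals `mean_Pa` exactly; the pulse amplitude is therefore
#' proportional to the mean.
#'
#' @param mean_Pa Target mean aortic pressure, mmHg.
#' @param period Cardiac cycle duration, s.
#' @param n_steps Timesteps per cycle (>= 16).
#' @param constant If `TRUE`, a degenerate constant waveform (all samples
#'   equal `mean_Pa`), useful for steady-state checks.
#' @return Object of class `pressure_waveform` with `times` (s) and
#'   `samples` (mmHg).
#' @export
make_waveform <- function(mean_Pa, period = 1.0, n_steps = 120,
                          constant = FALSE) {
  if (mean_Pa <= 0 || period <= 0) stop("mean_Pa and period must be positive")
  if (n_steps < 16) stop("n_steps must be at least 16")
  t <- (seq_len(n_steps) - 1) / n_steps * period
  if (constant) {
    samples <- rep(mean_Pa, n_steps)
  } else {
    tau <- t / period
    shape <- 1 + 0.16 * sin(2 * pi * tau - 0.9) + 0.07 * sin(4 * pi * tau + 0.8)
    samples <- mean_Pa * shape / mean(shape)
  }
  structure(list(period = period, n_steps = as.integer(n_steps),
                 times = t, samples = samples, mean_target = mean_Pa),
            class = "pressure_waveform")
}

# Poiseuille resistance of the lumen between two axial stations, mmHg s/ml.
# Integrand 128 mu / (pi d^4) is piecewise analytic; integrate per segment.
conduit_resistance <- function(geom, blood, z_from = 0,
                               z_to = geom$z3 + geom$L_out) {
  stopifnot(z_from <= z_to)
  check_domain(geom, c(z_from, z_to))
  brk <- sort(unique(pmin(pmax(c(z_from, geom$z0, geom$z1, geom$z2, geom$z3,
                                 z_to), z_from), z_to)))
  integrand <- function(z) 128 * blood$mu / (pi * (diameter_profile(geom, z) * 1e-3)^4)
  R_si <- 0
  for (k in seq_len(length(brk) - 1L)) {
    if (brk[k + 1L] > brk[k]) {
      R_si <- R_si + stats::integrate(integrand, brk[k], brk[k + 1L],
                                      rel.tol = 1e-10)$value
    }
  }
  R_si * 1e-3 * RES_SI_TO_CLIN   # dz was in mm
}

# Borda-Carnot-type expansion loss coefficient K so that
# dP_exp = K * Q * |Q| with Q in ml/s and dP in mmHg.
expansion_coefficient <- function(geom, blood, Kt = 1.52) {
  A_throat <- pi * (geom$D * (1 - geom$s0) / 2 * 1e-3)^2
  A_ref <- pi * (geom$D / 2 * 1e-3)^2
  K_si <- Kt * blood$density / 2 * (1 / A_throat - 1 / A_ref)^2
  K_si * 1e-12 / PA_PER_MMHG     # Q^2 in (ml/s)^2
}

#' Stenosis/conduit pressure drop at a given flow
#'
#' Reduced-order pressure-loss model over the whole conduit:
#' `dP(Q) = Rv Q + K Q |Q|` with `Rv` the axial integral of the local
#' Poiseuille resistance `128 mu / (pi d(z)^4)` (straight conduits, ramps
#' and throat) and `K` an empirical Borda-Carnot expansion-loss coefficient
#' `Kt (rho/2) (1/A_throat - 1/A_ref)^2` for the post-throat flow
#' separation. Strictly increasing in `Q`, zero at `Q = 0`, and unbounded
#' as `s0 -> 1`.
#'
#' @param geom A [stenosis_geometry()].
#' @param blood A [blood_properties()].
#' @param Q Flow rate(s), ml/s.
#' @param Kt Empirical expansion-loss constant.
#' @param lossless If `TRUE` the conduit is ideal (`dP = 0`); used for
#'   network sanity checks.
#' @return Pressure drop(s), mmHg.
#' @export
stenosis_dp <- function(geom, blood, Q, Kt = 1.52, lossless = FALSE) {
  stopifnot(all(is.finite(Q)))
  if (lossless) return(rep(0, length(Q)))
  Rv <- conduit_resistance(geom, blood)
  K <- expansion_coefficient(geom, blood, Kt)
  Rv * Q + K * Q * abs(Q)
}

# Solve, per timestep, Pa(t) - dP_conduit(Q) - R_eff Q - Pv = 0 for Q >= 0.
# Rv, K precomputed; bracketed scalar root finding to 1e-10 ml/s.
solve_cycle_resistive <- function(Pa_t, Rv, K, R_eff, Pv, tol = 1e-10) {
  vapply(Pa_t, function(pa) {
    drive <- pa - Pv
    if (drive <= 0) return(0)
    Qhi <- drive / R_eff + 1          # dP >= R_eff Q ensures root below
    g <- function(Q) drive - Rv * Q - K * Q * abs(Q) - R_eff * Q
    stats::uniroot(g, c(0, Qhi), tol = tol)$root
  }, numeric(1))
}

# Compliance branch: capacitor at the conduit/microcirculation junction.
# C dPc/dt = Q_in - (Pc - Pv)/R_eff, with Pa - dP(Q_in) - Pc = 0.
# Implicit Euler per step, marched over cycles to periodicity.
solve_cycle_compliant <- function(Pa_t, Rv, K, R_eff, Pv, C, dt,
                                  tol = 1e-10, max_cycles = 200) {
  n <- length(Pa_t)
  Pc <- mean(Pa_t)
  mean_prev <- Inf
  for (cyc in seq_len(max_cycles)) {
    Q <- numeric(n)
    for (k in seq_len(n)) {
      pa <- Pa_t[k]
      g <- function(Qn) {
        Pcn <- pa - (Rv * Qn + K * Qn * abs(Qn))
        C * (Pcn - Pc) / dt - (Qn - (Pcn - Pv) / R_eff)
      }
      Qhi <- max((pa - Pv) / R_eff, 0) + abs(C * (pa - Pc) / dt) + 1
      Q[k] <- stats::uniroot(g, c(-Qhi, Qhi), tol = tol, extendInt = "downX")$root
      Pc <- pa - (Rv * Q[k] + K * Q[k] * abs(Q[k]))
    }
    m <- mean(Q)
    if (abs(m - mean_prev) < 1e-8) return(Q)
    mean_prev <- m
  }
  stop("compliant LPN failed to reach a periodic state")
}

#' Transient reduced-order solve of the coupled stenosis + outlet network
#'
#' At every timestep of the cardiac cycle the series network balance
#' `Pa(t) - dP_conduit(Q) - R_eff Q - Pv = 0` is solved for the flow `Q(t)`
#' by bracketed scalar root finding (tolerance 1e-10 ml/s), with
#' `R_eff = R_multiplier * R_micro_base * hyperemia_factor` under hyperemia
#' and without the factor at baseline. Cycles are repeated until the
#' cycle-mean flow is periodic (change < 1e-8 ml/s) and the last cycle is
#' reported. The distal pressure is evaluated 20 mm downstream of the
#' stenosis end.
#'
#' @param geom A [stenosis_geometry()].
#' @param blood A [blood_properties()].
#' @param lpn An [lpn_params()] with calibrated `R_micro_base`.
#' @param waveform A [make_waveform()] inlet pressure trace.
#' @param condition `"baseline"` or `"hyperemia"`.
#' @param Kt Expansion-loss constant, see [stenosis_dp()].
#' @param lossless Ideal (lossless) conduit switch for network checks.
#' @param measurement_offset Distance of the distal pressure plane
#'   downstream of the stenosis end, mm.
#' @return Object of class `hemo_result` with per-step series `Q_t`, `Pd_t`,
#'   `dP_sten_t`, the cycle-mean flow `mean_Q`, and the scalar `FFR`
#'   (hyperemia runs) or `AWSS_prox` (baseline runs).
#' @export
transient_solve <- function(geom, blood, lpn, waveform,
                            condition = c("baseline", "hyperemia"),
                            Kt = 1.52, lossless = FALSE,
                            measurement_offset = 20) {
  condition <- match.arg(condition)
  fac <- if (condition == "hyperemia") lpn$hyperemia_factor else 1
  R_eff <- lpn$R_multiplier * lpn$R_micro_base * fac
  if (lossless) {
    Rv <- 0; K <- 0; Rv_plane <- 0
  } else {
    Rv <- conduit_resistance(geom, blood)
    K <- expansion_coefficient(geom, blood, Kt)
    z_plane <- geom$z3 + measurement_offset
    if (z_plane > geom$z3 + geom$L_out)
      stop("measurement plane lies beyond the outlet conduit")
    Rv_plane <- conduit_resistance(geom, blood, 0, z_plane)
  }
  Pa_t <- waveform$samples
  dt <- waveform$period / waveform$n_steps
  if (lpn$C > 0) {
    Q <- solve_cycle_compliant(Pa_t, Rv, K, R_eff, lpn$Pv, lpn$C, dt)
  } else {
    # quasi-steady: timesteps decouple, so one pass is periodic; a second
    # pass confirms the cycle-to-cycle criterion.
    Q <- solve_cycle_resistive(Pa_t, Rv, K, R_eff, lpn$Pv)
    Q2 <- solve_cycle_resistive(Pa_t, Rv, K, R_eff, lpn$Pv)
    stopifnot(abs(mean(Q2) - mean(Q)) < 1e-8)
  }
  dP_sten <- Rv * Q + K * Q * abs(Q)
  Pd <- Pa_t - (Rv_plane * Q + K * Q * abs(Q))
  res <- structure(list(
    t = waveform$times, Pa_t = Pa_t, Q_t = Q, Pd_t = Pd,
    dP_sten_t = dP_sten, mean_Q = mean(Q),
    condition = condition, R_eff = R_eff,
    geom = geom, blood = blood, lpn = lpn, waveform = waveform,
    FFR = NA_real_, AWSS_prox = NA_real_
  ), class = "hemo_result")
  if (condition == "hyperemia") res$FFR <- compute_ffr(res)
  if (condition == "baseline") res$AWSS_prox <- compute_awss_prox(res)
  res
}

#' @export
print.hemo_result <- function(x, ...) {
  cat(sprintf("Reduced-order coronary solve (%s): mean Q = %.4g ml/s\n",
              x$condition, x$mean_Q))
  if (x$condition == "hyperemia")
    cat(sprintf("  FFR = %.4f\n", x$FFR))
  else
    cat(sprintf("  AWSS_prox = %.4g Pa\n", x$AWSS_prox))
  invisible(x)
}

#' Calibrate the baseline microcirculation resistance
#'
#' Finds `R_micro_base` such that the cycle-mean flow of a baseline
#' [transient_solve()] at the supplied (Table-1 mean) geometry and waveform
#' equals `target_mean_Q`, by root finding on the monotone map
#' `R -> mean Q(R)`. The calibration is done once at study means and held
#' fixed across samples; resistance uncertainty is carried by the sampled
#' normalized multiplier `R`.
#'
#' @inheritParams transient_solve
#' @param target_mean_Q Target cycle-mean baseline flow, ml/s.
#' @param Pv Venous pressure, mmHg.
#' @param interval Search bracket for the resistance, mmHg s/ml.
#' @return `R_micro_base` in mmHg s/ml.
#' @export
calibrate_rmicro <- function(geom, blood, waveform, target_mean_Q = 1.0,
                             Kt = 1.52, lossless = FALSE, Pv = 0,
                             interval = c(1e-2, 1e4)) {
  if (target_mean_Q <= 0) stop("target_mean_Q must be positive")
  f <- function(R) {
    lpn <- lpn_params(R_micro_base = R, R_multiplier = 1, Pv = Pv)
    transient_solve(geom, blood, lpn, waveform, condition = "baseline",
                    Kt = Kt, lossless = lossless)$mean_Q - target_mean_Q
  }
  if (f(interval[1]) < 0 || f(interval[2]) > 0)
    stop("calibration failure: no resistance in the bracket matches the target flow")
  r <- stats::uniroot(f, interval, tol = 1e-11)
  R <- r$root
  if (abs(f(R)) > 1e-6)
    stop("calibration failure: residual mean-flow error exceeds 1e-6 ml/s")
  R
}

#' Fractional flow reserve from a hyperemic solve
#'
#' FFR is the ratio of the cycle-mean distal pressure (20 mm downstream of
#' the stenosis) to the cycle-mean aortic pressure, the clinical
#' ratio-of-means convention.
#'
#' @param res A `hemo_result` from a hyperemia run.
#' @param waveform Inlet waveform; defaults to the one stored in `res`.
#' @return FFR, dimensionless in (0, 1].
#' @export
compute_ffr <- function(res, waveform = res$waveform) {
  if (res$condition != "hyperemia")
    stop("FFR is defined for hyperemic runs; got a baseline result")
  mean(res$Pd_t) / mean(waveform$samples)
}

#' Cycle- and space-averaged proximal wall shear stress
#'
#' Applies the Poiseuille wall-shear closure
#' `tau(z, t) = 32 mu Q(t) / (pi d(z)^3)` and averages uniformly over the
#' proximal converging segment `[z0, z1]` and over the cardiac cycle. WSS is
#' a baseline-condition quantity.
#'
#' @param res A `hemo_result` from a baseline run.
#' @param geom,blood Geometry and blood properties; default to those stored
#'   in `res`.
#' @return Average proximal WSS, Pa.
#' @export
compute_awss_prox <- function(res, geom = res$geom, blood = res$blood) {
  if (res$condition != "baseline")
    stop("AWSS_prox is defined for baseline runs; got a hyperemic result")
  inv_d3 <- stats::integrate(
    function(z) (diameter_profile(geom, z) * 1e-3)^-3,
    geom$z0, geom$z1, rel.tol = 1e-10)$value / geom$Li
  32 * blood$mu * (res$mean_Q * 1e-6) / pi * inv_d3
}

#' Write a per-run time series to CSV and the scalar record to JSON
#'
#' @param res A `hemo_result`.
#' @param csv_path,json_path Output paths; either may be `NULL` to skip.
#' @return `res`, invisibly.
#' @export
export_hemo_result <- function(res, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(data.frame(t_s = res$t, Pa_mmHg = res$Pa_t,
                                Q_ml_s = res$Q_t, Pd_mmHg = res$Pd_t),
                     csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(condition = res$condition, FFR = res$FFR,
                              AWSS_prox_Pa = res$AWSS_prox,
                              mean_Q_ml_s = res$mean_Q),
                         json_path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(res)
}
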