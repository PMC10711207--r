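# Shared fixtures: geometry/blood at study means and small helpers.

mean_geom <- function(...) stenosis_geometry(Li = 6, Lm = 6, Lo = 6,
                                             D = 3.6, s0 = 0.5, ...)

study_blood <- function() blood_properties()

# Constant-pressure waveform for steady-state checks.
steady_wf <- function(mean_Pa = 90) make_waveform(mean_Pa, constant = TRUE)

# A single uniform input Pa ~ U[81, 99], as in the closed-form moment checks.
pa_var <- function() list(uncertain_variable("Pa", mean = 90, rel_uncertainty = 0.10))

# Fit a PCE to a deterministic response over given variables.
fit_response <- function(vars, f, p, nps = 2, seed = 1) {
  iset <- build_index_set(length(vars), p)
  des <- lhs_sample(vars, required_samples(iset$Np, nps), seed)
  fit_pce(des, apply(des$values, 1, f), iset)
}
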