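test_that("waveform discretization hits the target mean exactly and scales linearly", {
  wf <- make_waveform(90, period = 1, n_steps = 120)
  expect_length(wf$samples, 120)
  expect_equal(mean(wf$samples), 90, tolerance = 1e-12)
  wf81 <- make_waveform(81, period = 1, n_steps = 120)
  expect_equal(wf81$samples, (81 / 90) * wf$samples)
  cw <- steady_wf(90)
  expect_equal(cw$samples, rep(90, 120))
  expect_error(make_waveform(-5), "positive")
  expect_error(make_waveform(90, n_steps = 8), "n_steps")
})

test_that("pressure-drop law is zero at rest, Poiseuille for a straight tube, superlinear", {
  blood <- study_blood()
  geom <- mean_geom()
  expect_equal(stenosis_dp(geom, blood, 0), 0)
  # straight tube: closed-form Poiseuille drop 128 mu L Q / (pi D^4)
  straight <- stenosis_geometry(6, 6, 6, 3.6, s0 = 0, L_in = 10, L_out = 25)
  L <- (straight$z3 + straight$L_out) * 1e-3
  Q_si <- 1e-6
  dp_pa <- 128 * blood$mu * L * Q_si / (pi * (3.6e-3)^4)
  expect_equal(stenosis_dp(straight, blood, 1), dp_pa / 133.322387415,
               tolerance = 1e-8)
  # quadratic expansion loss makes the drop superlinear in Q
  for (Q in c(0.5, 1, 2, 4)) {
    expect_gte(stenosis_dp(geom, blood, 2 * Q), 2 * stenosis_dp(geom, blood, Q))
  }
  expect_gt(stenosis_dp(geom, blood, 2), 2 * stenosis_dp(geom, blood, 1))
  # monotone increasing in Q
  Qs <- seq(0, 5, by = 0.5)
  expect_true(all(diff(stenosis_dp(geom, blood, Qs)) > 0))
})

test_that("pressure drop diverges with stenosis severity", {
  blood <- study_blood()
  dps <- vapply(c(0.3, 0.5, 0.7, 0.9), function(s0) {
    stenosis_dp(stenosis_geometry(6, 6, 6, 3.6, s0), blood, 1)
  }, numeric(1))
  expect_true(all(diff(dps) > 0))
  expect_gt(dps[4] / dps[1], 50)
  expect_error(stenosis_geometry(6, 6, 6, 3.6, s0 = 1), "s0")
})

test_that("microvascular calibration recovers the Ohmic value and is reproducible", {
  blood <- study_blood()
  geom <- mean_geom()
  # lossless conduit, constant 90 mmHg, target 1 ml/s: R = (Pa - Pv) / Q = 90
  R_ohm <- calibrate_rmicro(geom, blood, steady_wf(90), target_mean_Q = 1,
                            lossless = TRUE)
  expect_equal(R_ohm, 90, tolerance = 1e-6)
  # with conduit losses the series microvascular resistance must shrink
  wf <- make_waveform(90)
  R1 <- calibrate_rmicro(geom, blood, wf, target_mean_Q = 1)
  expect_lt(R1, 90)
  expect_gt(R1, 50)
  # fixed point: recalibration reproduces the value
  R2 <- calibrate_rmicro(geom, blood, wf, target_mean_Q = 1)
  expect_lt(abs(R1 - R2), 1e-9)
  # and the calibrated network actually delivers the target mean flow
  res <- transient_solve(geom, blood, lpn_params(R1), wf, "baseline")
  expect_equal(res$mean_Q, 1, tolerance = 1e-6)
  expect_error(calibrate_rmicro(geom, blood, wf, target_mean_Q = -1),
               "target_mean_Q")
})

test_that("lossless resistive network reduces to Ohm's law; hyperemia quarters resistance", {
  blood <- study_blood()
  geom <- stenosis_geometry(6, 6, 6, 3.6, s0 = 0)
  lpn <- lpn_params(R_micro_base = 90)
  rb <- transient_solve(geom, blood, lpn, steady_wf(90), "baseline",
                        lossless = TRUE)
  expect_equal(rb$Q_t, rep(1, 120), tolerance = 1e-9)
  rh <- transient_solve(geom, blood, lpn, steady_wf(90), "hyperemia",
                        lossless = TRUE)
  expect_equal(rh$Q_t, rep(4, 120), tolerance = 1e-9)
  expect_equal(rh$FFR, 1, tolerance = 1e-9)
  # hyperemia_factor = 1 makes the two conditions identical (switch check)
  lpn1 <- lpn_params(90, hyperemia_factor = 1)
  wf <- make_waveform(90)
  r1 <- transient_solve(geom, blood, lpn1, wf, "baseline")
  r2 <- transient_solve(geom, blood, lpn1, wf, "hyperemia")
  expect_equal(r1$Q_t, r2$Q_t)
})

test_that("the pressure budget closes at every timestep", {
  blood <- study_blood()
  geom <- mean_geom()
  wf <- make_waveform(90)
  R1 <- calibrate_rmicro(geom, blood, wf)
  for (cond in c("baseline", "hyperemia")) {
    res <- transient_solve(geom, blood, lpn_params(R1, R_multiplier = 1.07),
                           wf, cond)
    residual <- res$Pa_t - res$dP_sten_t - res$R_eff * res$Q_t
    expect_lt(max(abs(residual)), 1e-7)
    expect_true(all(res$Pd_t <= res$Pa_t + 1e-12))
    expect_true(all(res$Q_t > 0))
  }
})

test_that("hyperemic over baseline mean flow lands in the physiological 3-4x bracket", {
  blood <- study_blood()
  geom <- mean_geom()
  wf <- make_waveform(90)
  Rm <- calibrate_rmicro(geom, blood, wf)
  lpn <- lpn_params(Rm)
  rb <- transient_solve(geom, blood, lpn, wf, "baseline")
  rh <- transient_solve(geom, blood, lpn, wf, "hyperemia")
  ratio <- rh$mean_Q / rb$mean_Q
  expect_gt(ratio, 3)
  expect_lt(ratio, 4)
})

test_that("FFR decreases with stenosis severity and with stenosis length", {
  blood <- study_blood()
  wf <- make_waveform(90)
  Rm <- calibrate_rmicro(mean_geom(), blood, wf)
  lpn <- lpn_params(Rm)
  ffr <- vapply(seq(0.3, 0.7, by = 0.1), function(s0) {
    transient_solve(stenosis_geometry(6, 6, 6, 3.6, s0), blood, lpn, wf,
                    "hyperemia")$FFR
  }, numeric(1))
  expect_true(all(diff(ffr) < 0))
  expect_true(all(ffr > 0 & ffr <= 1))
  # doubling all three stenosis segment lengths lowers FFR
  f1 <- transient_solve(stenosis_geometry(6, 6, 6, 3.6, 0.5), blood, lpn, wf,
                        "hyperemia")$FFR
  f2 <- transient_solve(stenosis_geometry(12, 12, 12, 3.6, 0.5), blood, lpn,
                        wf, "hyperemia")$FFR
  expect_lt(f2, f1)
})

test_that("FFR uses the ratio-of-means convention and is Pa-invariant for a linear network", {
  blood <- study_blood()
  geom <- mean_geom()
  wf <- make_waveform(90)
  Rm <- calibrate_rmicro(geom, blood, wf)
  res <- transient_solve(geom, blood, lpn_params(Rm), wf, "hyperemia")
  ratio_of_means <- mean(res$Pd_t) / mean(res$Pa_t)
  mean_of_ratios <- mean(res$Pd_t / res$Pa_t)
  expect_equal(res$FFR, ratio_of_means)
  expect_false(isTRUE(all.equal(ratio_of_means, mean_of_ratios,
                                tolerance = 1e-10)))
  # with the quadratic loss switched off the network is linear, so FFR does
  # not depend on the aortic pressure level
  lpn <- lpn_params(Rm)
  f81 <- transient_solve(geom, blood, lpn, make_waveform(81), "hyperemia",
                         Kt = 0)$FFR
  f99 <- transient_solve(geom, blood, lpn, make_waveform(99), "hyperemia",
                         Kt = 0)$FFR
  expect_equal(f81, f99, tolerance = 1e-9)
  # with the loss on, the dependence reappears
  g81 <- transient_solve(geom, blood, lpn, make_waveform(81), "hyperemia")$FFR
  g99 <- transient_solve(geom, blood, lpn, make_waveform(99), "hyperemia")$FFR
  expect_gt(abs(g81 - g99), 1e-4)
  expect_error(compute_ffr(transient_solve(geom, blood, lpn, wf, "baseline")),
               "hyperemic")
})

test_that("proximal WSS matches the Poiseuille closure and grows with severity", {
  blood <- study_blood()
  # straight tube, steady 1 ml/s: tau = 32 mu Q / (pi d^3) = 0.802 Pa
  straight <- stenosis_geometry(6, 6, 6, 3.6, s0 = 0)
  res <- transient_solve(straight, blood, lpn_params(90), steady_wf(90),
                         "baseline", lossless = TRUE)
  tau_ref <- 32 * blood$mu * 1e-6 / (pi * (3.6e-3)^3)
  expect_equal(res$AWSS_prox, tau_ref, tolerance = 1e-6)
  expect_equal(tau_ref, 0.802, tolerance = 1e-3)
  # zero flow gives zero shear
  res0 <- transient_solve(straight, blood, lpn_params(90), steady_wf(90),
                          "baseline", lossless = TRUE)
  res0$mean_Q <- 0
  expect_equal(compute_awss_prox(res0), 0)
  # severity sweep at fixed calibration: narrowing raises the 1/d^3 average
  wf <- make_waveform(90)
  Rm <- calibrate_rmicro(mean_geom(), blood, wf)
  awss <- vapply(seq(0.3, 0.7, by = 0.1), function(s0) {
    transient_solve(stenosis_geometry(6, 6, 6, 3.6, s0), blood,
                    lpn_params(Rm), wf, "baseline")$AWSS_prox
  }, numeric(1))
  expect_true(all(diff(awss) > 0))
  expect_error(compute_awss_prox(
    transient_solve(straight, blood, lpn_params(90), wf, "hyperemia")),
    "baseline")
})

test_that("small outlet compliance perturbs the quasi-steady solution only slightly", {
  blood <- study_blood()
  geom <- mean_geom()
  wf <- make_waveform(90)
  Rm <- calibrate_rmicro(geom, blood, wf)
  r0 <- transient_solve(geom, blood, lpn_params(Rm), wf, "baseline")
  rc <- transient_solve(geom, blood, lpn_params(Rm, C = 1e-4), wf, "baseline")
  expect_equal(rc$mean_Q, r0$mean_Q, tolerance = 1e-3)
  # a real compliance buffers the microcirculation, so the conduit inflow
  # follows the aortic pulse more closely and becomes more pulsatile than
  # the purely resistive solution
  rbig <- transient_solve(geom, blood, lpn_params(Rm, C = 1e-2), wf, "baseline")
  expect_gt(sd(rbig$Q_t), sd(r0$Q_t))
})

test_that("per-run results export to CSV and JSON", {
  blood <- study_blood()
  geom <- mean_geom()
  wf <- make_waveform(90)
  res <- transient_solve(geom, blood, lpn_params(88), wf, "hyperemia")
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  export_hemo_result(res, csv, js)
  tab <- read.csv(csv)
  expect_equal(nrow(tab), 120)
  expect_named(tab, c("t_s", "Pa_mmHg", "Q_ml_s", "Pd_mmHg"))
  rec <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(rec$FFR, res$FFR)
  expect_equal(rec$mean_Q_ml_s, res$mean_Q)
})
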