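test_that("moment formulas agree with a Monte Carlo evaluation of the surrogate", {
  bench <- make_benchmark("quadratic_mixed")
  s <- benchmark_pipeline(bench, p = 2)$surrogate
  mv <- surrogate_mean_variance(s)
  X <- with(list(), {
    set.seed(123)
    matrix(runif(2e5 * 2, -1, 1), ncol = 2)
  })
  y <- predict(s, X)
  n <- length(y)
  se_mean <- sd(y) / sqrt(n)
  expect_lt(abs(mean(y) - mv["mean"]), 3 * se_mean)
  se_var <- sqrt((mean((y - mean(y))^4) - var(y)^2) / n)
  expect_lt(abs(var(y) - mv["variance"]), 3 * se_var)
  expect_error(surrogate_mean_variance(list()), "fitted")
})

test_that("additive models have Si = SiT; product models are pure interaction", {
  add <- benchmark_pipeline(make_benchmark("linear_additive"), p = 2)
  expect_equal(add$Si, add$SiT, tolerance = 1e-10)
  expect_equal(add$Si, c(X1 = 0.9, X2 = 0.1), tolerance = 1e-8)
  prod <- benchmark_pipeline(make_benchmark("product"), p = 2)
  expect_equal(prod$Si, c(X1 = 0, X2 = 0), tolerance = 1e-8)
  expect_equal(prod$SiT, c(X1 = 1, X2 = 1), tolerance = 1e-8)
})

test_that("index bounds 0 <= Si <= SiT <= 1 and the sum rules hold", {
  for (nm in c("linear_additive", "product", "quadratic_mixed")) {
    fit <- benchmark_pipeline(make_benchmark(nm), p = 3)
    tol <- 1e-8
    expect_true(all(fit$Si >= -tol & fit$SiT <= 1 + tol))
    expect_true(all(fit$SiT >= fit$Si - tol))
    expect_lte(sum(fit$Si), 1 + tol)
    expect_gte(sum(fit$SiT), sum(fit$Si) - tol)
  }
  # zero-variance surrogate: indices are undefined and say so
  vars <- pa_var()
  s <- fit_response(vars, function(x) 7, p = 2)
  expect_error(sobol_indices(s), "variance is zero")
})

test_that("Ishigami indices from the coefficient partition match the closed forms", {
  bench <- make_benchmark("ishigami")
  fit <- benchmark_pipeline(bench, p = 9, nps = 2, seed = 2)
  expect_equal(fit$Si, bench$truth$Si, tolerance = 0.01)
  expect_equal(fit$SiT, bench$truth$SiT, tolerance = 0.01)
  # headline closed-form values of the standard (a = 7, b = 0.1) setting
  expect_equal(unname(bench$truth$Si[1:2]), c(0.3139, 0.4424), tolerance = 1e-3)
  expect_equal(unname(bench$truth$Si[3]), 0)
  expect_equal(unname(bench$truth$SiT[3]), 0.2437, tolerance = 1e-3)
})

test_that("the MC conditional-variance oracle reproduces the partition indices", {
  for (nm in c("linear_additive", "product", "quadratic_mixed")) {
    fit <- benchmark_pipeline(make_benchmark(nm), p = 3)
    mc <- mc_sobol_oracle(fit$surrogate, n_mc = 4e4, seed = 11)
    expect_true(all(abs(mc$Si - fit$Si) <= 3 * mc$se_Si + 1e-12))
    expect_true(all(abs(mc$SiT - fit$SiT) <= 3 * mc$se_SiT + 1e-12))
  }
  # determinism under equal seeds
  s <- benchmark_pipeline(make_benchmark("product"), p = 2)$surrogate
  m1 <- mc_sobol_oracle(s, n_mc = 5e3, seed = 4)
  m2 <- mc_sobol_oracle(s, n_mc = 5e3, seed = 4)
  expect_identical(m1$Si, m2$Si)
  expect_identical(m1$SiT, m2$SiT)
})

test_that("density resampling recovers uniform quantiles and flags degeneracy", {
  # identity surrogate on Pa ~ U[81, 99]
  s <- fit_response(pa_var(), function(x) x[1], p = 1)
  di <- density_and_interval(s, n_resample = 1e5, seed = 3)
  expect_equal(di$pi95[1], 81.45, tolerance = 5e-4)
  expect_equal(di$pi95[2], 98.55, tolerance = 5e-4)
  expect_false(di$pdf_estimate$degenerate)
  expect_lt(abs(di$skewness), 0.05)
  # reproducible under the seed
  di2 <- density_and_interval(s, n_resample = 1e5, seed = 3)
  expect_identical(di$pi95, di2$pi95)
  # constant surrogate: degenerate density, collapsed interval
  sc <- fit_response(pa_var(), function(x) 5, p = 1)
  dc <- density_and_interval(sc, n_resample = 1e4, seed = 1)
  expect_true(dc$pdf_estimate$degenerate)
  expect_equal(dc$pi95, c(5, 5))
})

test_that("uq_report assembles moments, indices and intervals coherently", {
  fit <- benchmark_pipeline(make_benchmark("quadratic_mixed"), p = 2)
  rep <- uq_report(fit$surrogate, n_resample = 2e4, seed = 9)
  expect_s3_class(rep, "uq_report")
  expect_equal(rep$mean, fit$mean)
  expect_equal(rep$std, sqrt(rep$variance))
  expect_equal(rep$Si, fit$Si)
  expect_lt(rep$pi95[1], rep$pi95[2])
  tab <- sensitivity_table(rep)
  expect_named(tab, c("input", "Si", "SiT"))
  expect_equal(tab$Si, unname(fit$Si))
})

test_that("convergence grids report Table-style sample counts and stabilize in-span", {
  # a cheap 7-input model makes the full (p, nps) grid inexpensive
  vars <- default_study_inputs()
  runner <- function(x) sum(x * seq_along(x))
  tab <- convergence_study(runner, vars, p_list = 1:4, nps_list = c(1, 2),
                           seed = 5)
  expect_equal(nrow(tab), 8)
  expect_equal(tab$Np, rep(c(8, 36, 120, 330), each = 2))
  expect_equal(tab$Ns[tab$nps == 1], c(8, 36, 120, 330))
  expect_equal(tab$Ns[tab$nps == 2], c(16, 72, 240, 660))
  expect_equal(sum(tab$Ns), 1482)
  expect_true(all(tab$n_failed == 0))
  # a degree-2 response is converged for every p >= 2
  vars2 <- list(uncertain_variable("a", lower = -1, upper = 1),
                uncertain_variable("b", lower = -1, upper = 1))
  q <- function(x) x[1]^2 + 0.5 * x[2]
  tq <- convergence_study(q, vars2, p_list = 2:4, nps_list = 2, seed = 1)
  expect_equal(tq$Si_a, rep(tq$Si_a[1], 3), tolerance = 1e-8)
  expect_equal(tq$Si_b, rep(tq$Si_b[1], 3), tolerance = 1e-8)
  expect_equal(tq$mean, rep(tq$mean[1], 3), tolerance = 1e-8)
})

test_that("model failures are recorded per convergence cell, not fatal", {
  vars2 <- list(uncertain_variable("a", lower = 0, upper = 1),
                uncertain_variable("b", lower = 0, upper = 1))
  flaky <- function(x) { if (x[1] > 0.8) stop("boom"); x[1] + x[2] }
  tab <- convergence_study(flaky, vars2, p_list = 1, nps_list = c(1, 2),
                           seed = 3)
  # every Latin hypercube with Ns >= 5 places at least one point above 0.8
  expect_gt(sum(tab$n_failed), 0)
  # cells with enough surviving runs still produce a fit
  ok_cells <- (tab$Ns - tab$n_failed) >= tab$Np
  expect_true(all(is.finite(tab$mean[ok_cells])))
  expect_true(all(is.na(tab$mean[!ok_cells])))
})
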