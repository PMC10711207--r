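#' Surrogate mean and variance from the coefficient vector
#'
#' With an orthonormal basis the surrogate mean is the coefficient of the
#' all-zeros index and the variance is the sum of squares of all remaining
#' coefficients.
#'
#' @param s A fitted `pce_surrogate`.
#' @return Named numeric vector `c(mean, variance)`.
#' @export
surrogate_mean_variance <- function(s) {
  if (!inherits(s, "pce_surrogate") || is.null(s$coefficients))
    stop("need a fitted pce_surrogate")
  a <- s$coefficients
  c(mean = a[1], variance = sum(a[-1]^2))
}

#' Main and total Sobol indices from the coefficient partition
#'
#' For a PCE in an orthonormal basis with independent inputs, the main
#' (first-order) index of input `i` is the normalized sum of squared
#' coefficients whose multi-index is nonzero only in position `i`, and the
#' total index sums all coefficients whose multi-index is nonzero in
#' position `i` (possibly among others). This is the exact conditional
#' variance decomposition
#' `Si = Var(E(Y|Xi))/Var(Y)` and `SiT = 1 - Var(E(Y|X_-i))/Var(Y)`
#' evaluated in closed form on the expansion.
#'
#' @param s A fitted `pce_surrogate`.
#' @return List with named vectors `Si` and `SiT` (one entry per input).
#' @export
sobol_indices <- function(s) {
  a <- s$coefficients
  V <- sum(a[-1]^2)
  # treat round-off-level variance (relative to the mean) as exactly zero
  if (V <= 1e-24 * max(1, a[1]^2))
    stop("output variance is zero; Sobol indices are undefined")
  idx <- s$index_set$indices
  nm <- var_names(s$vars)
  a2 <- a^2
  Si <- SiT <- stats::setNames(numeric(s$index_set$n), nm)
  for (i in seq_len(s$index_set$n)) {
    in_i <- idx[, i] > 0L
    only_i <- in_i & rowSums(idx[, -i, drop = FALSE] > 0L) == 0L
    Si[i] <- sum(a2[only_i]) / V
    SiT[i] <- sum(a2[in_i]) / V
  }
  list(Si = Si, SiT = SiT)
}

#' Monte Carlo conditional-variance oracle for Sobol indices
#'
#' Independent pick-freeze (Saltelli/Jansen) estimates of the main and
#' total indices from surrogate evaluations, following the literal
#' conditional-variance definitions. Used to cross-validate the closed-form
#' coefficient partition of [sobol_indices()]; the estimates come with
#' Monte Carlo standard errors.
#'
#' @param s A fitted `pce_surrogate`.
#' @param n_mc Base sample size (>= 1e4 recommended).
#' @param seed Integer seed.
#' @return List with `Si`, `SiT`, `se_Si`, `se_SiT`, `n_mc`, `seed`.
#' @export
mc_sobol_oracle <- function(s, n_mc = 1e4, seed = 1) {
  n <- s$index_set$n
  b <- var_bounds(s$vars)
  draw <- with_seed(seed, function() {
    matrix(stats::runif(2 * n_mc * n), ncol = n)
  })
  span <- b[, "upper"] - b[, "lower"]
  scale_rows <- function(u) sweep(sweep(u, 2, span, `*`), 2, b[, "lower"], `+`)
  A <- scale_rows(draw[seq_len(n_mc), , drop = FALSE])
  B <- scale_rows(draw[n_mc + seq_len(n_mc), , drop = FALSE])
  fA <- predict(s, A)
  fB <- predict(s, B)
  V <- stats::var(c(fA, fB))
  nm <- var_names(s$vars)
  Si <- SiT <- se_Si <- se_SiT <- stats::setNames(numeric(n), nm)
  for (i in seq_len(n)) {
    ABi <- A
    ABi[, i] <- B[, i]
    fABi <- predict(s, ABi)
    ti <- fB * (fABi - fA)          # Saltelli 2010 main-effect elementary terms
    ui <- (fA - fABi)^2 / 2        # Jansen total-effect elementary terms
    Si[i] <- mean(ti) / V
    SiT[i] <- mean(ui) / V
    se_Si[i] <- stats::sd(ti) / sqrt(n_mc) / V
    se_SiT[i] <- stats::sd(ui) / sqrt(n_mc) / V
  }
  list(Si = Si, SiT = SiT, se_Si = se_Si, se_SiT = se_SiT,
       n_mc = n_mc, seed = seed)
}

#' Output density estimate and 95% prediction interval
#'
#' Draws `n_resample` joint-uniform inputs, evaluates the surrogate, and
#' returns a Freedman-Diaconis histogram plus a Gaussian kernel density,
#' the empirical (2.5, 97.5) percentile pair (linear-interpolation
#' quantiles) and the sample skewness.
#'
#' @param s A fitted `pce_surrogate`.
#' @param n_resample Number of resampled surrogate evaluations.
#' @param seed Integer seed.
#' @return List with `pdf_estimate` (histogram + kernel density), `pi95`,
#'   `skewness`, `mean`, `sd`, `n_resample`, `seed`.
#' @export
density_and_interval <- function(s, n_resample = 1e5, seed = 1) {
  n <- s$index_set$n
  b <- var_bounds(s$vars)
  X <- with_seed(seed, function() {
    u <- matrix(stats::runif(n_resample * n), ncol = n)
    sweep(sweep(u, 2, b[, "upper"] - b[, "lower"], `*`), 2, b[, "lower"], `+`)
  })
  y <- predict(s, X)
  m <- mean(y)
  sdev <- stats::sd(y)
  if (sdev == 0) {
    pdf_est <- list(degenerate = TRUE, value = m)
    skew <- 0
  } else {
    h <- graphics::hist(y, breaks = "FD", plot = FALSE)
    kd <- stats::density(y)
    pdf_est <- list(degenerate = FALSE,
                    breaks = h$breaks, counts = h$counts, density = h$density,
                    kernel_x = kd$x, kernel_y = kd$y)
    skew <- mean((y - m)^3) / sdev^3
  }
  pi95 <- unname(stats::quantile(y, c(0.025, 0.975), type = 7))
  list(pdf_estimate = pdf_est, pi95 = pi95, skewness = skew,
       mean = m, sd = sdev, n_resample = as.integer(n_resample),
       seed = seed)
}

#' Assemble a full uncertainty-quantification report from a surrogate
#'
#' Combines the closed-form moments, the coefficient-partition Sobol
#' indices and the resampled density/interval summary.
#'
#' @inheritParams density_and_interval
#' @return Object of class `uq_report`.
#' @export
uq_report <- function(s, n_resample = 1e5, seed = 1) {
  mv <- surrogate_mean_variance(s)
  sob <- sobol_indices(s)
  di <- density_and_interval(s, n_resample = n_resample, seed = seed)
  structure(list(mean = unname(mv["mean"]), variance = unname(mv["variance"]),
                 std = sqrt(unname(mv["variance"])),
                 Si = sob$Si, SiT = sob$SiT,
                 pdf_estimate = di$pdf_estimate, pi95 = di$pi95,
                 skewness = di$skewness,
                 n_resample = di$n_resample, seed = seed,
                 Np = s$index_set$Np, Ns = s$Ns, p = s$index_set$p),
            class = "uq_report")
}

#' @export
print.uq_report <- function(x, ...) {
  cat(sprintf("UQ report (p = %d, Np = %d, Ns = %d)\n", x$p, x$Np, x$Ns))
  cat(sprintf("  mean = %.6g, sd = %.4g, 95%% PI = [%.6g, %.6g], skewness = %.3f\n",
              x$mean, x$std, x$pi95[1], x$pi95[2], x$skewness))
  tab <- data.frame(Si = round(x$Si, 4), SiT = round(x$SiT, 4))
  print(tab)
  invisible(x)
}

#' Sensitivity table of a report (inputs x {Si, SiT})
#'
#' @param report A [uq_report()].
#' @param path Optional CSV path to write the table to.
#' @return A data frame with columns `input`, `Si`, `SiT`.
#' @export
sensitivity_table <- function(report, path = NULL) {
  tab <- data.frame(input = names(report$Si),
                    Si = unname(report$Si), SiT = unname(report$SiT))
  if (!is.null(path)) utils::write.csv(tab, path, row.names = FALSE)
  tab
}

#' Convergence study over polynomial order and oversampling ratio
#'
#' For every `(p, nps)` grid cell: builds the total-degree basis, draws a
#' fresh seeded Latin hypercube of `ceiling(nps * Np)` points, evaluates
#' the model at each sample, fits the surrogate and records moments and
#' sensitivity indices. Individual model failures are recorded per cell
#' (and their rows dropped from the fit) rather than aborting the grid.
#'
#' @param model_runner Function mapping a native-unit input vector to a
#'   scalar output.
#' @param vars List of [uncertain_variable()]s.
#' @param p_list Polynomial orders to scan.
#' @param nps_list Oversampling ratios to scan.
#' @param seed Base seed; each cell uses a distinct deterministic offset.
#' @return A data frame (class `convergence_table`) with one row per cell:
#'   `p`, `nps`, `Np`, `Ns`, `n_failed`, `mean`, `variance`, then `Si_*`
#'   and `SiT_*` columns per input.
#' @export
convergence_study <- function(model_runner, vars, p_list = 1:4,
                              nps_list = c(1, 2), seed = 1) {
  n <- length(vars)
  nm <- var_names(vars)
  rows <- list()
  cell <- 0L
  for (p in p_list) {
    for (nps in nps_list) {
      cell <- cell + 1L
      iset <- build_index_set(n, p)
      Ns <- required_samples(iset$Np, nps)
      des <- lhs_sample(vars, Ns, seed + cell - 1L)
      y <- apply(des$values, 1L, function(x) {
        tryCatch(model_runner(x), error = function(e) NA_real_)
      })
      ok <- !is.na(y)
      n_failed <- sum(!ok)
      row <- data.frame(p = p, nps = nps, Np = iset$Np, Ns = Ns,
                        n_failed = n_failed)
      if (sum(ok) >= iset$Np) {
        des_ok <- des
        des_ok$unit_coords <- des$unit_coords[ok, , drop = FALSE]
        des_ok$values <- des$values[ok, , drop = FALSE]
        des_ok$Ns <- sum(ok)
        s <- fit_pce(des_ok, y[ok], iset)
        mv <- surrogate_mean_variance(s)
        sob <- sobol_indices(s)
        row$mean <- mv["mean"]; row$variance <- mv["variance"]
        for (j in seq_len(n)) row[[paste0("Si_", nm[j])]] <- sob$Si[j]
        for (j in seq_len(n)) row[[paste0("SiT_", nm[j])]] <- sob$SiT[j]
      } else {
        row$mean <- NA_real_; row$variance <- NA_real_
        for (j in seq_len(n)) row[[paste0("Si_", nm[j])]] <- NA_real_
        for (j in seq_len(n)) row[[paste0("SiT_", nm[j])]] <- NA_real_
      }
      rows[[cell]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("convergence_table", "data.frame")
  out
}
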