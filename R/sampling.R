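#' Define a uniformly distributed uncertain input
#'
#' An uncertain variable is parameterized either by a mean and a symmetric
#' relative half-width (`bounds = mean * (1 -+ rel_uncertainty)`, the
#' convention used for the study inputs), or by explicit lower/upper bounds
#' (used e.g. by benchmark problems whose inputs are centered at zero).
#'
#' @param name Variable identifier.
#' @param mean Mean value in native units (for uniform inputs, the interval
#'   midpoint). May be omitted when `lower`/`upper` are given.
#' @param rel_uncertainty Dimensionless relative half-width (0.05 for "5%").
#' @param lower,upper Explicit interval bounds, overriding the relative
#'   parameterization.
#' @param distribution Only `"uniform"` is supported.
#' @return An object of class `uncertain_variable`.
#' @export
uncertain_variable <- function(name, mean = NULL, rel_uncertainty = NULL,
                               lower = NULL, upper = NULL,
                               distribution = "uniform") {
  distribution <- match.arg(distribution, "uniform")
  if (is.null(lower) || is.null(upper)) {
    if (is.null(mean) || is.null(rel_uncertainty))
      stop("give either (mean, rel_uncertainty) or (lower, upper)")
    lower <- mean * (1 - rel_uncertainty)
    upper <- mean * (1 + rel_uncertainty)
  }
  if (is.null(mean)) mean <- (lower + upper) / 2
  if (!(lower < upper)) stop("lower bound must be strictly below upper bound")
  structure(list(name = name, mean = mean,
                 rel_uncertainty = rel_uncertainty,
                 lower = lower, upper = upper,
                 distribution = distribution),
            class = "uncertain_variable")
}

#' @export
print.uncertain_variable <- function(x, ...) {
  cat(sprintf("%s ~ U[%g, %g] (mean %g)\n", x$name, x$lower, x$upper, x$mean))
  invisible(x)
}

var_names <- function(vars) vapply(vars, `[[`, character(1), "name")
var_bounds <- function(vars) {
  cbind(lower = vapply(vars, `[[`, numeric(1), "lower"),
        upper = vapply(vars, `[[`, numeric(1), "upper"))
}
var_means <- function(vars) {
  stats::setNames(vapply(vars, `[[`, numeric(1), "mean"), var_names(vars))
}

#' The seven uncertain inputs of the coronary stenosis study
#'
#' Returns the study's uncertain-input table: the three stenosis segment
#' lengths (6 mm, 5%), the reference lumen diameter (3.6 mm, 5%), the degree
#' of stenosis (50%, 5% relative), the mean aortic pressure (90 mmHg, 10%)
#' and the normalized microcirculation resistance (1, 10%). All are
#' independent uniforms with bounds `mean * (1 -+ u)`. The stenosis
#' eccentricity is deliberately absent: it is held fixed at 35% and does not
#' enter the reduced-order solver.
#'
#' @return A list of 7 [uncertain_variable()] objects named
#'   `Li, Lm, Lo, D, s0, Pa, R`.
#' @export
default_study_inputs <- function() {
  list(
    uncertain_variable("Li", mean = 6.0, rel_uncertainty = 0.05),
    uncertain_variable("Lm", mean = 6.0, rel_uncertainty = 0.05),
    uncertain_variable("Lo", mean = 6.0, rel_uncertainty = 0.05),
    uncertain_variable("D",  mean = 3.6, rel_uncertainty = 0.05),
    uncertain_variable("s0", mean = 0.5, rel_uncertainty = 0.05),
    uncertain_variable("Pa", mean = 90,  rel_uncertainty = 0.10),
    uncertain_variable("R",  mean = 1.0, rel_uncertainty = 0.10)
  )
}

# Run fn with the RNG seeded to `seed`, restoring the caller's RNG state.
with_seed <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Seeded Latin hypercube design over uncertain inputs
#'
#' Draws an `Ns x n` Latin hypercube: each column is an independent random
#' permutation of the `Ns` equal-probability strata of `[0, 1]`, with the
#' point placed at the stratum midpoint (default; deterministic given the
#' permutation and well-conditioned for least squares) or jittered uniformly
#' within its stratum. Unit coordinates are mapped affinely to the native
#' variable bounds. Identical `(vars, Ns, seed, method)` reproduce the
#' design bitwise.
#'
#' @param vars List of [uncertain_variable()]s.
#' @param Ns Number of samples (>= 1).
#' @param seed Integer seed driving all column permutations.
#' @param method `"midpoint"` or `"jitter"` within-stratum placement.
#' @return An object of class `sample_matrix` with elements `unit_coords`
#'   and `values` (`Ns x n` matrices), `seed`, `n`, `Ns`, `method`, `vars`.
#' @export
lhs_sample <- function(vars, Ns, seed, method = c("midpoint", "jitter")) {
  method <- match.arg(method)
  if (Ns < 1) stop("Ns must be at least 1")
  Ns <- as.integer(Ns)
  n <- length(vars)
  unit <- with_seed(seed, function() {
    u <- matrix(NA_real_, Ns, n)
    for (j in seq_len(n)) {
      perm <- sample.int(Ns)
      u[, j] <- if (method == "midpoint") (perm - 0.5) / Ns
                else (perm - stats::runif(Ns)) / Ns
    }
    u
  })
  b <- var_bounds(vars)
  vals <- sweep(sweep(unit, 2, b[, "upper"] - b[, "lower"], `*`),
                2, b[, "lower"], `+`)
  colnames(unit) <- colnames(vals) <- var_names(vars)
  structure(list(unit_coords = unit, values = vals, seed = seed,
                 n = n, Ns = Ns, method = method, vars = vars),
            class = "sample_matrix")
}

#' @export
as.data.frame.sample_matrix <- function(x, ...) as.data.frame(x$values)

#' @export
print.sample_matrix <- function(x, ...) {
  cat(sprintf("Latin hypercube design: Ns = %d, n = %d, seed = %d (%s)\n",
              x$Ns, x$n, x$seed, x$method))
  print(utils::head(as.data.frame(x)))
  invisible(x)
}

#' Write a design to CSV (one row per sample, header = variable names)
#'
#' @param design A [lhs_sample()] design.
#' @param path Output CSV path.
#' @export
write_design <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE)
  invisible(path)
}
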