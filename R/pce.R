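#' Total-degree multi-index set
#'
#' Enumerates all `n`-tuples of nonnegative integers with component sum at
#' most `p`, in graded ordering (by total degree, then lexicographic with
#' the first component decreasing). The count is the binomial
#' `Np = (n + p)! / (n! p!)`; the first index is the all-zeros tuple.
#'
#' @param n Number of inputs (>= 1).
#' @param p Total polynomial order (>= 0).
#' @return Object of class `multi_index_set` with `indices` (`Np x n`
#'   integer matrix), `n`, `p`, `Np`.
#' @export
build_index_set <- function(n, p) {
  if (n < 1 || p < 0) stop("need n >= 1 and p >= 0")
  n <- as.integer(n); p <- as.integer(p)
  compositions <- function(m, g) {
    if (m == 1L) return(matrix(g, 1L, 1L))
    do.call(rbind, lapply(seq.int(g, 0L), function(k) {
      cbind(k, compositions(m - 1L, g - k))
    }))
  }
  idx <- do.call(rbind, lapply(0:p, function(g) compositions(n, g)))
  dimnames(idx) <- NULL
  storage.mode(idx) <- "integer"
  stopifnot(nrow(idx) == choose(n + p, p))
  structure(list(n = n, p = p, indices = idx, Np = nrow(idx)),
            class = "multi_index_set")
}

#' @export
print.multi_index_set <- function(x, ...) {
  cat(sprintf("Total-degree multi-index set: n = %d, p = %d, Np = %d\n",
              x$n, x$p, x$Np))
  invisible(x)
}

#' Number of collocation samples for an oversampling ratio
#'
#' `Ns = ceiling(nps * Np)`; `nps = 1` gives a square collocation system,
#' `nps = 2` the recommended two-fold oversampling for least squares.
#'
#' @param Np Number of expansion terms.
#' @param nps Oversampling ratio (>= 1).
#' @return Integer sample count.
#' @export
required_samples <- function(Np, nps) {
  if (nps < 1) stop("nps < 1 would give an under-determined system")
  as.integer(ceiling(nps * Np))
}

# Orthonormal Legendre polynomials on [-1, 1] w.r.t. the uniform density:
# matrix length(x) x (pmax + 1), column k+1 = sqrt(2k + 1) P_k(x).
legendre_orthonormal <- function(pmax, x) {
  out <- matrix(NA_real_, length(x), pmax + 1L)
  Pkm1 <- rep(1, length(x))
  out[, 1L] <- Pkm1
  if (pmax >= 1L) {
    Pk <- x
    out[, 2L] <- sqrt(3) * Pk
    if (pmax >= 2L) {
      for (k in 1L:(pmax - 1L)) {
        Pkp1 <- ((2 * k + 1) * x * Pk - k * Pkm1) / (k + 1)
        out[, k + 2L] <- sqrt(2 * (k + 1) + 1) * Pkp1
        Pkm1 <- Pk
        Pk <- Pkp1
      }
    }
  }
  out
}

# Map native-unit inputs (matrix or vector) to the standard interval [-1,1].
to_standard <- function(vars, x) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  b <- var_bounds(vars)
  sweep(sweep(x, 2, b[, "lower"], `-`), 2,
        (b[, "upper"] - b[, "lower"]) / 2, `/`) - 1
}

# Design matrix of tensorized orthonormal Legendre basis functions at
# standard coordinates U (rows = points).
basis_matrix <- function(index_set, U) {
  one_d <- lapply(seq_len(index_set$n), function(j) {
    legendre_orthonormal(index_set$p, U[, j])
  })
  Psi <- matrix(1, nrow(U), index_set$Np)
  for (k in seq_len(index_set$Np)) {
    for (j in seq_len(index_set$n)) {
      deg <- index_set$indices[k, j]
      if (deg > 0L) Psi[, k] <- Psi[, k] * one_d[[j]][, deg + 1L]
    }
  }
  Psi
}

#' Evaluate the tensorized orthonormal basis at native-unit points
#'
#' Inputs are mapped affinely to the standard interval per variable and the
#' tensor products of one-dimensional orthonormal Legendre polynomials are
#' evaluated; the entry for the all-zeros index is identically 1.
#'
#' @param index_set A [build_index_set()].
#' @param x Native-unit input point (length-`n` vector) or `m x n` matrix.
#' @param vars The uncertain variables defining the affine transforms.
#' @return A length-`Np` vector (single point) or `m x Np` matrix.
#' @export
evaluate_basis <- function(index_set, x, vars) {
  single <- !is.matrix(x)
  U <- to_standard(vars, x)
  if (ncol(U) != index_set$n) stop("input dimension does not match index set")
  Psi <- basis_matrix(index_set, U)
  if (single) drop(Psi) else Psi
}

#' Fit a polynomial chaos surrogate by least-squares collocation
#'
#' Solves `min_alpha ||Psi alpha - y||_2` over the design points via QR
#' decomposition, where `Psi` is the matrix of orthonormal basis functions
#' evaluated at the (standardized) design. Requires `Ns >= Np`; the design
#' matrix condition number is computed by SVD and fitting aborts when it
#' exceeds 1e10 or the matrix is rank deficient.
#'
#' @param design A [lhs_sample()] design (carries the variables/transforms).
#' @param y Model outputs aligned with the design rows.
#' @param index_set A [build_index_set()] with matching `n`.
#' @return Object of class `pce_surrogate` with `coefficients`,
#'   `index_set`, `vars`, `condition_number`, `residual_norm`, `Ns`.
#' @export
fit_pce <- function(design, y, index_set) {
  stopifnot(inherits(design, "sample_matrix"))
  y <- as.numeric(y)
  if (length(y) != design$Ns) stop("design and outputs are not aligned rowwise")
  if (anyNA(y)) stop("outputs contain missing values; drop failed runs first")
  if (design$n != index_set$n) stop("design dimension does not match index set")
  if (design$Ns < index_set$Np)
    stop(sprintf("under-determined system: Ns = %d < Np = %d",
                 design$Ns, index_set$Np))
  U <- 2 * design$unit_coords - 1
  Psi <- basis_matrix(index_set, U)
  sv <- svd(Psi, nu = 0, nv = 0)$d
  cond <- sv[1] / sv[length(sv)]
  if (!is.finite(cond) || cond > 1e10 || sv[length(sv)] <= 0)
    stop(sprintf("rank-deficient or ill-conditioned design matrix (condition number %.3g)",
                 cond))
  qrd <- qr(Psi)
  alpha <- qr.coef(qrd, y)
  structure(list(coefficients = as.numeric(alpha), index_set = index_set,
                 vars = design$vars, condition_number = cond,
                 residual_norm = sqrt(sum(qr.resid(qrd, y)^2)),
                 Ns = design$Ns),
            class = "pce_surrogate")
}

#' @export
print.pce_surrogate <- function(x, ...) {
  mv <- surrogate_mean_variance(x)
  cat(sprintf("PCE surrogate: n = %d, p = %d, Np = %d, Ns = %d\n",
              x$index_set$n, x$index_set$p, x$index_set$Np, x$Ns))
  cat(sprintf("  mean = %.6g, variance = %.6g; cond(Psi) = %.3g, ||resid|| = %.3g\n",
              mv["mean"], mv["variance"], x$condition_number, x$residual_norm))
  invisible(x)
}

#' Evaluate a fitted surrogate at native-unit points
#'
#' @param object A `pce_surrogate`.
#' @param newdata Native-unit point (vector) or `m x n` matrix.
#' @param ... Unused.
#' @return Predicted output(s).
#' @export
predict.pce_surrogate <- function(object, newdata, ...) {
  Psi <- evaluate_basis(object$index_set, newdata, object$vars)
  if (is.matrix(Psi)) drop(Psi %*% object$coefficients)
  else sum(Psi * object$coefficients)
}

#' Serialize a fitted surrogate to JSON (and load it back)
#'
#' Stores the multi-index set, coefficients and per-variable affine
#' transforms so the surrogate can be reloaded exactly.
#'
#' @param s A `pce_surrogate`.
#' @param path JSON file path.
#' @return `write_surrogate`: `path` invisibly; `read_surrogate`: the
#'   reconstructed `pce_surrogate`.
#' @export
write_surrogate <- function(s, path) {
  b <- var_bounds(s$vars)
  jsonlite::write_json(list(
    n = s$index_set$n, p = s$index_set$p,
    indices = s$index_set$indices,
    coefficients = s$coefficients,
    variables = data.frame(name = var_names(s$vars),
                           lower = b[, "lower"], upper = b[, "upper"]),
    condition_number = s$condition_number,
    residual_norm = s$residual_norm, Ns = s$Ns
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_surrogate
#' @export
read_surrogate <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  iset <- build_index_set(obj$n, obj$p)
  stopifnot(all(iset$indices == obj$indices))
  vars <- lapply(seq_len(nrow(obj$variables)), function(i) {
    uncertain_variable(obj$variables$name[i], lower = obj$variables$lower[i],
                       upper = obj$variables$upper[i])
  })
  structure(list(coefficients = as.numeric(obj$coefficients),
                 index_set = iset, vars = vars,
                 condition_number = obj$condition_number,
                 residual_norm = obj$residual_norm, Ns = obj$Ns),
            class = "pce_surrogate")
}
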