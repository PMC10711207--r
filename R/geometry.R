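#' Idealized eccentric coronary stenosis geometry
#'
#' Constructs the parametric description of a single stenosed coronary
#' conduit: a straight inlet segment, a converging (proximal) ramp, a
#' constant-diameter throat, a diverging (distal) ramp and a straight outlet
#' segment. The lumen diameter narrows sinusoidally from the reference
#' diameter `D` to `D * (1 - s0)` at the throat, and the centerline is offset
#' towards +y by up to `e0 = eps0 * s0 * D / 2` to model an eccentric lesion.
#'
#' Axial positions `z` are measured in mm from the inlet plane, so the
#' stenosis occupies `[z0, z3]` with `z0 = L_in`, `z1 = z0 + Li`,
#' `z2 = z1 + Lm` and `z3 = z2 + Lo`.
#'
#' @param Li,Lm,Lo Proximal (converging), middle (throat) and distal
#'   (diverging) stenosis segment lengths, mm.
#' @param D Reference (healthy) lumen diameter, mm.
#' @param s0 Degree of stenosis: fractional diameter reduction at the throat,
#'   in `[0, 1)`.
#' @param eps0 Eccentricity fraction in `[0, 1)`: 0 is concentric, values
#'   near 1 push the throat wall to the reference lumen boundary.
#' @param L_in,L_out Straight inlet/outlet conduit lengths, mm. The defaults
#'   (10 and 25 mm) keep the distal pressure measurement plane, 20 mm
#'   downstream of the stenosis, inside the modelled domain.
#' @return An object of class `stenosis_geometry`.
#' @examples
#' geom <- stenosis_geometry(Li = 6, Lm = 6, Lo = 6, D = 3.6, s0 = 0.5)
#' diameter_profile(geom, geom$z1)   # throat diameter 1.8 mm
#' @export
stenosis_geometry <- function(Li, Lm, Lo, D, s0, eps0 = 0.35,
                              L_in = 10, L_out = 25) {
  stopifnot(is.numeric(Li), is.numeric(Lm), is.numeric(Lo), is.numeric(D))
  if (any(c(Li, Lm, Lo, D, L_in, L_out) <= 0))
    stop("Li, Lm, Lo, D, L_in and L_out must all be positive")
  if (s0 < 0 || s0 >= 1) stop("s0 must lie in [0, 1)")
  if (eps0 < 0 || eps0 >= 1) stop("eps0 must lie in [0, 1)")
  z0 <- L_in
  geom <- list(
    Li = Li, Lm = Lm, Lo = Lo, D = D, s0 = s0, eps0 = eps0,
    L_in = L_in, L_out = L_out,
    z0 = z0, z1 = z0 + Li, z2 = z0 + Li + Lm, z3 = z0 + Li + Lm + Lo,
    e0 = eps0 * s0 * D / 2
  )
  class(geom) <- "stenosis_geometry"
  geom
}

#' @export
print.stenosis_geometry <- function(x, ...) {
  cat("Idealized stenotic coronary geometry\n")
  cat(sprintf("  segments Li/Lm/Lo: %.3g / %.3g / %.3g mm; D = %.3g mm\n",
              x$Li, x$Lm, x$Lo, x$D))
  cat(sprintf("  stenosis s0 = %.1f%% (throat %.3g mm), eccentricity %.1f%% (e0 = %.3g mm)\n",
              100 * x$s0, x$D * (1 - x$s0), 100 * x$eps0, x$e0))
  cat(sprintf("  domain z in [0, %.3g] mm; stenosis on [%.3g, %.3g]\n",
              x$z3 + x$L_out, x$z0, x$z3))
  invisible(x)
}

check_domain <- function(geom, z) {
  if (any(z < 0 - 1e-12) || any(z > geom$z3 + geom$L_out + 1e-12))
    stop(sprintf("axial position outside modelled domain [0, %g] mm",
                 geom$z3 + geom$L_out))
  invisible(TRUE)
}

#' Lumen diameter along the vessel axis
#'
#' Piecewise profile: constant `D` on the straight conduits, a sine
#' narrowing on the converging ramp, constant `D (1 - s0)` over the throat
#' and a cosine recovery on the diverging ramp. Continuous at all four
#' junctions.
#'
#' @param geom A [stenosis_geometry()].
#' @param z Axial position(s), mm, inside `[0, z3 + L_out]`.
#' @return Diameter(s) in mm.
#' @export
diameter_profile <- function(geom, z) {
  check_domain(geom, z)
  d <- rep(geom$D, length(z))
  s0 <- geom$s0; D <- geom$D
  i <- z >= geom$z0 & z <= geom$z1
  d[i] <- D * (1 - s0 * sin(pi / (2 * geom$Li) * (z[i] - geom$z0)))
  i <- z > geom$z1 & z <= geom$z2
  d[i] <- D * (1 - s0)
  i <- z > geom$z2 & z <= geom$z3
  d[i] <- D * (1 - s0 * cos(pi / (2 * geom$Lo) * (z[i] - geom$z2)))
  d
}

#' Centerline offset along the vessel axis
#'
#' The stenotic segment's axis is shifted towards +y, ramping up
#' sinusoidally over the converging segment to the maximum off-center
#' distance `e0 = eps0 * s0 * D / 2`, held constant over the throat, and
#' ramping back down over the diverging segment. Zero on the straight
#' conduits.
#'
#' @inheritParams diameter_profile
#' @return Offset(s) in mm.
#' @export
centerline_offset <- function(geom, z) {
  check_domain(geom, z)
  e <- rep(0, length(z))
  i <- z >= geom$z0 & z <= geom$z1
  e[i] <- geom$e0 * sin(pi / (2 * geom$Li) * (z[i] - geom$z0))
  i <- z > geom$z1 & z <= geom$z2
  e[i] <- geom$e0
  i <- z > geom$z2 & z <= geom$z3
  e[i] <- geom$e0 * cos(pi / (2 * geom$Lo) * (z[i] - geom$z2))
  e
}

#' Cross-sectional lumen contour at an axial station
#'
#' The lumen cross-section is a circle of diameter `d(z)` centered at
#' `(0, e(z))`; the returned loop is closed (first point repeated last).
#'
#' @inheritParams diameter_profile
#' @param z A single axial position, mm.
#' @param n_theta Number of distinct points around the circumference (>= 8).
#' @return A `(n_theta + 1) x 2` matrix of (x, y) coordinates in mm.
#' @export
cross_section_contour <- function(geom, z, n_theta = 64) {
  stopifnot(length(z) == 1L)
  if (n_theta < 8) stop("n_theta must be at least 8")
  d <- diameter_profile(geom, z)
  e <- centerline_offset(geom, z)
  theta <- seq(0, 2 * pi, length.out = n_theta + 1)
  cbind(x = d / 2 * cos(theta), y = e + d / 2 * sin(theta))
}

#' Tabulate the lumen profile along the axis
#'
#' @inheritParams diameter_profile
#' @param n Number of uniformly spaced axial stations.
#' @return A data frame with columns `z_mm`, `d_mm`, `e_mm`, `area_mm2`.
#' @export
geometry_table <- function(geom, n = 200) {
  z <- seq(0, geom$z3 + geom$L_out, length.out = n)
  d <- diameter_profile(geom, z)
  data.frame(z_mm = z, d_mm = d, e_mm = centerline_offset(geom, z),
             area_mm2 = pi * (d / 2)^2)
}

#' Write the centerline/diameter table to CSV
#'
#' @inheritParams geometry_table
#' @param path Output CSV path.
#' @return The table, invisibly.
#' @export
export_centerline <- function(geom, path, n = 200) {
  tab <- geometry_table(geom, n)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}

#' Export the lofted lumen surface as STL or legacy VTK
#'
#' Tessellates the tube swept by [cross_section_contour()] contours on a
#' structured (z, theta) grid; quads are split into triangles consistently,
#' and the tube can be capped with triangle fans so the surface is
#' watertight. The vertex count is `axial_resolution * n_theta` plus two cap
#' centers when capped.
#'
#' @inheritParams diameter_profile
#' @param path Output file path.
#' @param axial_resolution Number of axial stations (>= 2).
#' @param n_theta Number of circumferential points per station (>= 8).
#' @param format `"stl"` (ASCII) or `"vtk"` (legacy polydata).
#' @param capped Close the inlet/outlet with triangle fans?
#' @return Invisibly, a list with `vertices` (N x 3 matrix, mm), `faces`
#'   (M x 3 integer matrix, 1-based) and `path`.
#' @export
export_surface <- function(geom, path, axial_resolution = 120, n_theta = 48,
                           format = c("stl", "vtk"), capped = TRUE) {
  format <- match.arg(format)
  if (axial_resolution < 2) stop("axial_resolution must be at least 2")
  if (n_theta < 8) stop("n_theta must be at least 8")
  z <- seq(0, geom$z3 + geom$L_out, length.out = axial_resolution)
  theta <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  d <- diameter_profile(geom, z)
  e <- centerline_offset(geom, z)
  verts <- do.call(rbind, lapply(seq_along(z), function(k) {
    cbind(d[k] / 2 * cos(theta), e[k] + d[k] / 2 * sin(theta), z[k])
  }))
  idx <- function(k, j) (k - 1L) * n_theta + ((j - 1L) %% n_theta) + 1L
  faces <- vector("list", axial_resolution - 1L)
  for (k in seq_len(axial_resolution - 1L)) {
    j <- seq_len(n_theta)
    a <- idx(k, j); b <- idx(k, j + 1L)
    cc <- idx(k + 1L, j + 1L); dd <- idx(k + 1L, j)
    faces[[k]] <- rbind(cbind(a, b, cc), cbind(a, cc, dd))
  }
  faces <- do.call(rbind, faces)
  if (capped) {
    c_in <- nrow(verts) + 1L
    c_out <- nrow(verts) + 2L
    verts <- rbind(verts,
                   c(0, e[1], z[1]),
                   c(0, e[axial_resolution], z[axial_resolution]))
    j <- seq_len(n_theta)
    # inlet normal faces -z: wind clockwise seen from +z
    faces <- rbind(faces,
                   cbind(rep(c_in, n_theta), idx(1L, j + 1L), idx(1L, j)),
                   cbind(rep(c_out, n_theta), idx(axial_resolution, j),
                         idx(axial_resolution, j + 1L)))
  }
  dimnames(verts) <- NULL
  dimnames(faces) <- NULL
  switch(format,
         stl = write_stl_ascii(verts, faces, path),
         vtk = write_vtk_polydata(verts, faces, path))
  invisible(list(vertices = verts, faces = faces, path = path))
}

write_stl_ascii <- function(verts, faces, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid lumen", con)
  v1 <- verts[faces[, 1], , drop = FALSE]
  v2 <- verts[faces[, 2], , drop = FALSE]
  v3 <- verts[faces[, 3], , drop = FALSE]
  u <- v2 - v1; w <- v3 - v1
  nrm <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
               u[, 3] * w[, 1] - u[, 1] * w[, 3],
               u[, 1] * w[, 2] - u[, 2] * w[, 1])
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  out <- character(7L * nrow(faces))
  for (f in seq_len(nrow(faces))) {
    base <- 7L * (f - 1L)
    out[base + 1L] <- sprintf(" facet normal %.9e %.9e %.9e",
                              nrm[f, 1], nrm[f, 2], nrm[f, 3])
    out[base + 2L] <- "  outer loop"
    out[base + 3L] <- sprintf("   vertex %.9e %.9e %.9e", v1[f, 1], v1[f, 2], v1[f, 3])
    out[base + 4L] <- sprintf("   vertex %.9e %.9e %.9e", v2[f, 1], v2[f, 2], v2[f, 3])
    out[base + 5L] <- sprintf("   vertex %.9e %.9e %.9e", v3[f, 1], v3[f, 2], v3[f, 3])
    out[base + 6L] <- "  endloop"
    out[base + 7L] <- " endfacet"
  }
  writeLines(out, con)
  writeLines("endsolid lumen", con)
  invisible(path)
}

write_vtk_polydata <- function(verts, faces, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "stenosis lumen surface",
               "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(verts))), con)
  writeLines(sprintf("%.9e %.9e %.9e", verts[, 1], verts[, 2], verts[, 3]), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(faces), 4L * nrow(faces)), con)
  writeLines(sprintf("3 %d %d %d", faces[, 1] - 1L, faces[, 2] - 1L,
                     faces[, 3] - 1L), con)
  invisible(path)
}
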