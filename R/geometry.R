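# Exact geometric primitives shared by surface extraction and sphere
# fitting. All coordinates are world millimetres, never voxel indices.

as_point3 <- function(p, what = "point") {
  p <- as.numeric(p)
  if (length(p) != 3L || !all(is.finite(p))) {
    stop_hipwear(sprintf("%s must be 3 finite coordinates (mm)", what),
                 "hipwear_invalid_input")
  }
  p
}

#' Construct a sphere model
#'
#' A sphere is a center in world millimetres plus a positive radius; it is
#' the common currency between the phantom ground truth, the fitting stage
#' and the wear analysis.
#'
#' @param center Numeric length-3, center in mm.
#' @param radius Positive radius in mm.
#' @return An object of class `sphere_model` with elements `center`, `radius`.
#' @export
sphere_model <- function(center, radius) {
  center <- as_point3(center, "center")
  radius <- as.numeric(radius)
  if (length(radius) != 1L || !is.finite(radius) || radius <= 0) {
    stop_hipwear("radius must be a single positive number (mm)",
                 "hipwear_invalid_input")
  }
  structure(list(center = center, radius = radius), class = "sphere_model")
}

#' @export
print.sphere_model <- function(x, ...) {
  cat(sprintf("<sphere_model> center (%.4f, %.4f, %.4f) mm, radius %.4f mm\n",
              x$center[1], x$center[2], x$center[3], x$radius))
  invisible(x)
}

#' Fit a plane through three noncolinear points
#'
#' Used for the cup-rim plane defined by the three rim landmarks.
#'
#' @param p1,p2,p3 Numeric length-3 points (mm).
#' @param tol Minimum triangle area (mm^2) below which the points are
#'   considered colinear.
#' @return An object of class `plane` with a `point` on the plane and a unit
#'   `normal`.
#' @export
fit_plane <- function(p1, p2, p3, tol = 1e-9) {
  p1 <- as_point3(p1); p2 <- as_point3(p2); p3 <- as_point3(p3)
  n <- cross3(p2 - p1, p3 - p1)
  area <- sqrt(sum(n^2)) / 2
  if (!is.finite(area) || area < tol) {
    stop_hipwear("points are coincident or colinear; cannot define a plane",
                 "hipwear_degenerate_geometry")
  }
  structure(list(point = p1, normal = n / sqrt(sum(n^2))), class = "plane")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Shortest distance from a point to a plane
#'
#' @param p Numeric length-3 point (mm).
#' @param plane A `plane` from [fit_plane()].
#' @return Nonnegative distance in mm.
#' @export
point_plane_distance <- function(p, plane) {
  p <- as_point3(p)
  stopifnot(inherits(plane, "plane"))
  abs(sum((p - plane$point) * plane$normal))
}

#' Circumsphere of four points
#'
#' The unique sphere through four non-coplanar points; the elementary
#' estimate underlying the robust fit, which draws many random four-point
#' subsets of the extracted surface.
#'
#' @param p1,p2,p3,p4 Numeric length-3 points (mm).
#' @param vol_tol Minimum tetrahedron volume (mm^3) below which the quadruple
#'   is rejected as coplanar.
#' @return A [sphere_model()].
#' @export
circumsphere <- function(p1, p2, p3, p4, vol_tol = 1e-6) {
  P <- rbind(as_point3(p1), as_point3(p2), as_point3(p3), as_point3(p4))
  res <- circumsphere_batch(P[1, , drop = FALSE], P[2, , drop = FALSE],
                            P[3, , drop = FALSE], P[4, , drop = FALSE],
                            vol_tol = vol_tol)
  if (!res$ok[1]) {
    stop_hipwear("four points are (near-)coplanar; circumsphere is undefined",
                 "hipwear_degenerate_geometry")
  }
  sphere_model(res$center[1, ], res$radius[1])
}

# Vectorised circumspheres. P1..P4 are m x 3 matrices; returns centers
# (m x 3), radii (m), and ok flags (tetrahedron volume >= vol_tol).
# Solves 2 (p_i - p_4) . c = |p_i|^2 - |p_4|^2 for i = 1..3 by Cramer's rule.
circumsphere_batch <- function(P1, P2, P3, P4, vol_tol = 1e-6) {
  A1 <- P1 - P4; A2 <- P2 - P4; A3 <- P3 - P4
  b1 <- 0.5 * (rowSums(P1^2) - rowSums(P4^2))
  b2 <- 0.5 * (rowSums(P2^2) - rowSums(P4^2))
  b3 <- 0.5 * (rowSums(P3^2) - rowSums(P4^2))
  # det of rows (A1; A2; A3) via scalar triple product
  cx <- A2[, 2] * A3[, 3] - A2[, 3] * A3[, 2]
  cy <- A2[, 3] * A3[, 1] - A2[, 1] * A3[, 3]
  cz <- A2[, 1] * A3[, 2] - A2[, 2] * A3[, 1]
  det <- A1[, 1] * cx + A1[, 2] * cy + A1[, 3] * cz
  vol <- abs(det) / 6
  ok <- is.finite(vol) & vol >= vol_tol
  d <- ifelse(ok, det, NA_real_)
  # Cramer: replace column k of (A1;A2;A3) by b
  repcol <- function(k) {
    M1 <- A1; M2 <- A2; M3 <- A3
    M1[, k] <- b1; M2[, k] <- b2; M3[, k] <- b3
    M1[, 1] * (M2[, 2] * M3[, 3] - M2[, 3] * M3[, 2]) +
      M1[, 2] * (M2[, 3] * M3[, 1] - M2[, 1] * M3[, 3]) +
      M1[, 3] * (M2[, 1] * M3[, 2] - M2[, 2] * M3[, 1])
  }
  center <- cbind(repcol(1) / d, repcol(2) / d, repcol(3) / d)
  radius <- sqrt(rowSums((P4 - center)^2))
  list(center = center, radius = radius, ok = ok)
}
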