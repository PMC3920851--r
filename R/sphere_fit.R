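# Robust sphere fitting: random four-point circumspheres, a radius histogram
# for initialisation, two pruning passes that discard points which keep
# contributing to off-radius circumspheres, then geometric least squares on
# the survivors.

#' Configure the robust sphere fit
#'
#' Defaults follow the published procedure: 80,000 random quadruples with
#' every pair at least 2 mm apart, a 1000-bin radius histogram, a coarse
#' prune at +/-2 mm and a fine prune at twice the slice thickness
#' (+/-0.4 mm at 0.2 mm slices).
#'
#' @param n_samples Number of admissible quadruples per pass.
#' @param min_pair_separation Minimum pairwise distance within a quadruple,
#'   mm (avoids degenerate circumspheres).
#' @param n_histogram_bins Number of radius-histogram bins.
#' @param histogram_range Radius range (mm) spanned by the histogram. The
#'   default 0-100 mm covers all plausible implant radii at 0.1 mm per bin.
#' @param coarse_tolerance,fine_tolerance Radius deviation (mm) beyond which
#'   a circumsphere counts against its four member points, for the first and
#'   second pruning pass.
#' @param offending_mode `"relative"` (default) removes a point when the
#'   offending fraction of its quadruple participations exceeds
#'   `offending_fraction`; `"absolute"` removes a point when its offending
#'   count exceeds `offending_count_threshold`, as in the published absolute
#'   rule (meaningful only for matching sample and point counts).
#' @param offending_fraction Offending-participation fraction cutoff for
#'   relative mode. 0.7 separates inliers from outliers for contamination up
#'   to ~25%: a quadruple offends if any member is an outlier, so an
#'   inlier's offending fraction stays near `1 - (1 - c)^3` while an
#'   outlier's is near 1.
#' @param offending_count_threshold Absolute offending-count cutoff.
#' @param min_participation Points sampled fewer times than this are never
#'   pruned (insufficient evidence).
#' @param rng_seed Integer seed; each pass uses a derived sub-seed.
#' @return A `fit_config` list.
#' @export
fit_config <- function(n_samples = 80000L,
                       min_pair_separation = 2,
                       n_histogram_bins = 1000L,
                       histogram_range = c(0, 100),
                       coarse_tolerance = 2,
                       fine_tolerance = 0.4,
                       offending_mode = c("relative", "absolute"),
                       offending_fraction = 0.7,
                       offending_count_threshold = 1600L,
                       min_participation = 8L,
                       rng_seed = 1L) {
  offending_mode <- match.arg(offending_mode)
  if (n_samples <= 0) {
    stop_hipwear("n_samples must be positive", "hipwear_configuration_error")
  }
  if (coarse_tolerance <= 0 || fine_tolerance <= 0 ||
      fine_tolerance >= coarse_tolerance) {
    stop_hipwear("need 0 < fine_tolerance < coarse_tolerance",
                 "hipwear_configuration_error")
  }
  structure(list(n_samples = as.integer(n_samples),
                 min_pair_separation = min_pair_separation,
                 n_histogram_bins = as.integer(n_histogram_bins),
                 histogram_range = as.numeric(histogram_range),
                 coarse_tolerance = coarse_tolerance,
                 fine_tolerance = fine_tolerance,
                 offending_mode = offending_mode,
                 offending_fraction = offending_fraction,
                 offending_count_threshold = as.integer(offending_count_threshold),
                 min_participation = as.integer(min_participation),
                 rng_seed = as.integer(rng_seed)),
            class = "fit_config")
}

points_matrix <- function(points, valid_only = TRUE) {
  if (is.matrix(points)) return(points)
  if (valid_only && "valid" %in% names(points)) {
    points <- points[points$valid, ]
  }
  as.matrix(points[, c("x_mm", "y_mm", "z_mm")])
}

as_surface_points <- function(points) {
  if (is.matrix(points)) {
    points <- tibble(x_mm = points[, 1], y_mm = points[, 2], z_mm = points[, 3])
  }
  points <- as_tibble(points)
  if (!"offending" %in% names(points)) points$offending <- 0L
  if (!"participation" %in% names(points)) points$participation <- 0L
  if (!"valid" %in% names(points)) points$valid <- TRUE
  points
}

#' Sample admissible four-point subsets
#'
#' Draws exactly `cfg$n_samples` quadruples of valid points whose six
#' pairwise distances all reach `cfg$min_pair_separation`, by seeded batch
#' rejection sampling.
#'
#' @param points A surface-point tibble (or plain n x 3 matrix).
#' @param cfg A [fit_config()].
#' @param seed Seed for this pass (defaults to `cfg$rng_seed`).
#' @return Integer matrix `n_samples` x 4 of row indices into the valid
#'   points (indices refer to rows of the full table).
#' @export
sample_quadruples <- function(points, cfg, seed = cfg$rng_seed) {
  points <- as_surface_points(points)
  idx_valid <- which(points$valid)
  P <- as.matrix(points[idx_valid, c("x_mm", "y_mm", "z_mm")])
  n <- nrow(P)
  if (n < 4L || max(apply(P, 2, function(v) diff(range(v)))) <=
      cfg$min_pair_separation) {
    stop_hipwear(
      "too few valid points, or points too tightly clustered, to sample quadruples",
      "hipwear_insufficient_points")
  }
  out <- matrix(0L, cfg$n_samples, 4)
  got <- 0L
  drawn <- 0L
  max_draw <- 50L * cfg$n_samples + 1000L
  minsep2 <- cfg$min_pair_separation^2
  withr::with_seed(seed, {
    while (got < cfg$n_samples) {
      batch <- min(as.integer(1.5 * (cfg$n_samples - got)) + 64L,
                   max_draw - drawn)
      if (batch <= 0L) {
        stop_hipwear(
          "could not find enough admissible quadruples; points may be degenerate",
          "hipwear_insufficient_points")
      }
      drawn <- drawn + batch
      q <- matrix(sample.int(n, 4L * batch, replace = TRUE), batch, 4)
      ok <- rep(TRUE, batch)
      for (a in 1:3) for (b in (a + 1):4) {
        d2 <- rowSums((P[q[, a], , drop = FALSE] -
                         P[q[, b], , drop = FALSE])^2)
        ok <- ok & d2 >= minsep2
      }
      q <- q[ok, , drop = FALSE]
      take <- min(nrow(q), cfg$n_samples - got)
      if (take > 0L) {
        out[got + seq_len(take), ] <- q[seq_len(take), ]
        got <- got + take
      }
    }
  })
  matrix(idx_valid[out], nrow(out), 4)
}

quad_circumspheres <- function(points, quads, cfg) {
  P <- points_matrix(as_surface_points(points), valid_only = FALSE)
  circumsphere_batch(P[quads[, 1], , drop = FALSE],
                     P[quads[, 2], , drop = FALSE],
                     P[quads[, 3], , drop = FALSE],
                     P[quads[, 4], , drop = FALSE])
}

#' Initial radius and center from the circumsphere radius histogram
#'
#' Histograms the circumsphere radii of one pass of random quadruples; the
#' center of the fullest bin is the initial radius (ties broken toward the
#' larger radius), and the initial center is the component-wise median of
#' the circumsphere centers falling in that bin.
#'
#' @inheritParams sample_quadruples
#' @return List with `initial_radius`, `initial_center`, `n_quadruples`.
#' @export
initial_radius_estimate <- function(points, cfg, seed = cfg$rng_seed) {
  points <- as_surface_points(points)
  quads <- sample_quadruples(points, cfg, seed = seed)
  cs <- quad_circumspheres(points, quads, cfg)
  lo <- cfg$histogram_range[1]; hi <- cfg$histogram_range[2]
  bw <- (hi - lo) / cfg$n_histogram_bins
  ok <- cs$ok & cs$radius > lo & cs$radius <= hi
  if (!any(ok)) {
    stop_hipwear("all sampled quadruples were degenerate or out of range",
                 "hipwear_fitting_error")
  }
  bin <- pmin(ceiling((cs$radius[ok] - lo) / bw), cfg$n_histogram_bins)
  counts <- tabulate(bin, nbins = cfg$n_histogram_bins)
  best <- max(which(counts == max(counts)))
  in_bin <- which(ok)[bin == best]
  list(initial_radius = lo + (best - 0.5) * bw,
       initial_center = apply(cs$center[in_bin, , drop = FALSE], 2, median),
       n_quadruples = sum(ok))
}

#' Prune points that repeatedly produce off-radius circumspheres
#'
#' Runs a fresh pass of random quadruples; every quadruple whose circumsphere
#' radius deviates from `initial_radius` by more than `tolerance` increments
#' the offending count of its four member points. Points whose offending
#' statistic is too high (relative or absolute rule, see [fit_config()]) are
#' marked invalid. The valid set never grows.
#'
#' @param points A surface-point tibble.
#' @param initial_radius Reference radius, mm.
#' @param tolerance Allowed radius deviation, mm.
#' @param cfg A [fit_config()].
#' @param seed Seed for this pass.
#' @return The surface-point tibble with updated `offending`,
#'   `participation` and `valid` columns.
#' @export
prune_landmarks <- function(points, initial_radius, tolerance, cfg,
                            seed = cfg$rng_seed) {
  points <- as_surface_points(points)
  quads <- sample_quadruples(points, cfg, seed = seed)
  cs <- quad_circumspheres(points, quads, cfg)
  offending_quad <- !cs$ok | abs(cs$radius - initial_radius) > tolerance
  npts <- nrow(points)
  part <- tabulate(as.vector(quads), nbins = npts)
  off <- tabulate(as.vector(quads[offending_quad, , drop = FALSE]),
                  nbins = npts)
  points$participation <- points$participation + part
  points$offending <- points$offending + off
  bad <- if (cfg$offending_mode == "absolute") {
    off > cfg$offending_count_threshold
  } else {
    part >= cfg$min_participation & off / pmax(part, 1L) > cfg$offending_fraction
  }
  points$valid <- points$valid & !bad
  if (!any(points$valid)) {
    stop_hipwear("pruning removed every surface point",
                 "hipwear_fitting_error")
  }
  points
}

#' Geometric least-squares sphere fit
#'
#' Minimises the sum of squared orthogonal residuals `(|p - c| - r)^2` by
#' Gauss-Newton, initialised from the algebraic (Coope) linear fit.
#'
#' @param points n x 3 matrix or surface-point tibble (valid rows used) of
#'   at least four non-coplanar points.
#' @return A [sphere_model()].
#' @export
least_squares_sphere <- function(points) {
  P <- points_matrix(points)
  if (nrow(P) < 4L) {
    stop_hipwear("need at least 4 points to fit a sphere",
                 "hipwear_insufficient_points")
  }
  ctr <- colMeans(P)
  sv <- svd(sweep(P, 2, ctr), nu = 0, nv = 0)$d
  if (sv[3] < 1e-9 * max(sv[1], 1)) {
    stop_hipwear("points are coplanar; sphere fit is degenerate",
                 "hipwear_degenerate_geometry")
  }
  # algebraic initialisation: |p|^2 = 2 p.c + (r^2 - |c|^2)
  A <- cbind(2 * P, 1)
  b <- rowSums(P^2)
  beta <- qr.coef(qr(A), b)
  c0 <- beta[1:3]
  r0 <- sqrt(max(beta[4] + sum(c0^2), .Machine$double.eps))
  # Gauss-Newton on (|p - c| - r)
  cc <- c0; r <- r0
  for (it in seq_len(100)) {
    dvec <- sweep(P, 2, cc)
    di <- sqrt(rowSums(dvec^2))
    di <- pmax(di, 1e-12)
    res <- di - r
    J <- cbind(-dvec / di, -1)
    step <- tryCatch(qr.coef(qr(J), -res), error = function(e) rep(0, 4))
    step[!is.finite(step)] <- 0
    cc <- cc + step[1:3]
    r <- r + step[4]
    if (sqrt(sum(step^2)) < 1e-12) break
  }
  sphere_model(cc, r)
}

#' Robust sphere fit
#'
#' The full three-stage procedure: histogram initialisation, a coarse prune
#' at `coarse_tolerance`, a fine prune at `fine_tolerance` (fresh seeded
#' quadruple streams per pass), then geometric least squares over the
#' surviving valid points.
#'
#' @param points A surface-point tibble from the extraction stage (or an
#'   n x 3 matrix).
#' @param cfg A [fit_config()].
#' @return An object of class `sphere_fit`: elements `center`, `radius`,
#'   `initial_center`, `initial_radius`, `n_initial_points`,
#'   `n_valid_points`, `rms_residual` and the annotated `points` tibble.
#' @export
fit_sphere <- function(points, cfg = fit_config()) {
  points <- as_surface_points(points)
  n0 <- sum(points$valid)
  init <- initial_radius_estimate(points, cfg, seed = cfg$rng_seed)
  points <- prune_landmarks(points, init$initial_radius,
                            cfg$coarse_tolerance, cfg,
                            seed = cfg$rng_seed + 1L)
  points <- prune_landmarks(points, init$initial_radius,
                            cfg$fine_tolerance, cfg,
                            seed = cfg$rng_seed + 2L)
  model <- least_squares_sphere(points)
  P <- points_matrix(points)
  res <- sqrt(rowSums(sweep(P, 2, model$center)^2)) - model$radius
  structure(list(center = model$center,
                 radius = model$radius,
                 initial_center = init$initial_center,
                 initial_radius = init$initial_radius,
                 n_initial_points = n0,
                 n_valid_points = sum(points$valid),
                 rms_residual = sqrt(mean(res^2)),
                 points = points,
                 config = cfg),
            class = "sphere_fit")
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "<sphere_fit> radius %.4f mm (initial %.2f), center (%.4f, %.4f, %.4f)\n",
    "  %d / %d points valid after pruning, RMS residual %.4f mm\n"),
    x$radius, x$initial_radius, x$center[1], x$center[2], x$center[3],
    x$n_valid_points, x$n_initial_points, x$rms_residual))
  invisible(x)
}

#' @describeIn fit_sphere Broom-style one-row-per-parameter summary.
#' @param x A `sphere_fit`.
#' @param ... Unused.
#' @method tidy sphere_fit
#' @export
tidy.sphere_fit <- function(x, ...) {
  tibble(term = c("center_x", "center_y", "center_z", "radius", "diameter"),
         estimate = c(x$center, x$radius, 2 * x$radius))
}

#' @describeIn fit_sphere Broom-style one-row fit summary.
#' @method glance sphere_fit
#' @export
glance.sphere_fit <- function(x, ...) {
  tibble(radius = x$radius, diameter = 2 * x$radius,
         initial_radius = x$initial_radius,
         n_initial_points = x$n_initial_points,
         n_valid_points = x$n_valid_points,
         rms_residual = x$rms_residual)
}
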