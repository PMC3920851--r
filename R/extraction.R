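# Threshold-limited ray search for candidate surface points, constrained by
# the seven operator landmarks. Rays step inward with trilinear intensity
# interpolation; a crossing requires a run of at least `min_run_length`
# consecutive samples above threshold, so isolated above-threshold voxels
# are ignored, and the reported point is the linear threshold crossing just
# before the qualifying run (sub-step precision, no half-step inward bias).

#' Configure surface extraction
#'
#' @param threshold Intensity threshold separating implant metal from
#'   everything else.
#' @param cup_range_fraction Fraction of the starting radius a cup ray may
#'   travel before giving up; limits penetration through unused screw holes.
#' @param min_run_length Consecutive above-threshold samples required before
#'   a crossing counts as surface ("consistently exceeds" rule).
#' @param n_ray_directions Number of ray directions (hemisphere for the cup,
#'   full sphere for the head).
#' @param step_size Sampling step along each ray, mm. Default (`NULL`) is
#'   half the smallest voxel spacing of the volume being searched.
#' @param rim_margin_mm Cup rays aimed closer than this to the rim plane are
#'   skipped (default 1 mm): at the very rim the shell is cut off and meets
#'   the liner, so threshold crossings there do not lie on the spherical
#'   surface.
#' @param radius_landmark Which landmark defines the cup starting radius:
#'   the apical point (`"apex"`, the default) or the offset point
#'   (`"cup_offset"`).
#' @return An `extraction_config` list.
#' @export
extraction_config <- function(threshold,
                              cup_range_fraction = 0.60,
                              min_run_length = 3L,
                              n_ray_directions = 4000L,
                              step_size = NULL,
                              rim_margin_mm = 1,
                              radius_landmark = c("apex", "cup_offset")) {
  radius_landmark <- match.arg(radius_landmark)
  if (!is.finite(threshold)) {
    stop_hipwear("threshold must be finite", "hipwear_configuration_error")
  }
  if (cup_range_fraction <= 0 || cup_range_fraction > 1) {
    stop_hipwear("cup_range_fraction must be in (0, 1]",
                 "hipwear_configuration_error")
  }
  if (min_run_length < 1L) {
    stop_hipwear("min_run_length must be at least 1",
                 "hipwear_configuration_error")
  }
  structure(list(threshold = threshold,
                 cup_range_fraction = cup_range_fraction,
                 min_run_length = as.integer(min_run_length),
                 n_ray_directions = as.integer(n_ray_directions),
                 step_size = step_size,
                 rim_margin_mm = rim_margin_mm,
                 radius_landmark = radius_landmark),
            class = "extraction_config")
}

#' Starting radius for the cup surface search
#'
#' The shortest distance from the rim plane to the point centered in the
#' apical dome hole (or, optionally, to the offset point).
#'
#' @param cup_rim_plane A `plane` from [fit_plane()] on the rim landmarks.
#' @param apex The apical (or offset) landmark, mm.
#' @return Positive distance in mm.
#' @export
starting_radius <- function(cup_rim_plane, apex) {
  d <- point_plane_distance(apex, cup_rim_plane)
  if (d < 1e-6) {
    stop_hipwear("apical point lies on the rim plane; starting radius undefined",
                 "hipwear_degenerate_geometry")
  }
  d
}

# Deterministic, uniform direction samples: Fibonacci spiral on the unit
# sphere, or on the +z hemisphere (then rotated so +z maps to `axis`).
fibonacci_directions <- function(n, hemisphere = FALSE, axis = c(0, 0, 1)) {
  i <- seq_len(n) - 0.5
  z <- if (hemisphere) i / n else 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  rho <- sqrt(pmax(1 - z^2, 0))
  u <- cbind(rho * cos(phi), rho * sin(phi), z)
  axis <- axis / sqrt(sum(axis^2))
  if (sum(abs(axis - c(0, 0, 1))) < 1e-12) return(u)
  # rotate +z onto axis (Rodrigues)
  v <- cross3(c(0, 0, 1), axis)
  s <- sqrt(sum(v^2)); cth <- axis[3]
  if (s < 1e-12) return(u %*% diag(c(1, 1, -1)))  # axis == -z
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  R <- diag(3) + K + K %*% K * ((1 - cth) / s^2)
  u %*% t(R)
}

# Core ray caster. starts: n x 3 start points; dirs: n x 3 unit directions
# (inward); travel capped at max_travel (scalar or per-ray). Returns a
# surface-point tibble; rays whose very first window is already above
# threshold are treated as starting inside metal and discarded.
cast_rays <- function(vol, starts, dirs, max_travel, step, threshold,
                      min_run_length) {
  n_steps <- as.integer(floor(max(max_travel) / step)) + 1L
  tvals <- (seq_len(n_steps) - 1) * step
  n <- nrow(starts)
  pts <- cbind(
    rep(starts[, 1], n_steps) + outer(dirs[, 1], tvals)[seq_len(n * n_steps)],
    rep(starts[, 2], n_steps) + outer(dirs[, 2], tvals)[seq_len(n * n_steps)],
    rep(starts[, 3], n_steps) + outer(dirs[, 3], tvals)[seq_len(n * n_steps)])
  vals <- interp_trilinear(vol, pts, outside = -Inf)
  above <- matrix(vals > threshold, n, n_steps)
  if (length(max_travel) > 1L || max(max_travel) > min(max_travel)) {
    above <- above & outer(rep(1, n), tvals) <= max_travel
  } else {
    above[, tvals > max_travel[1]] <- FALSE
  }
  run <- above
  L <- min_run_length
  if (L > 1L) {
    for (k in seq_len(L - 1L)) {
      shifted <- cbind(above[, -seq_len(k), drop = FALSE],
                       matrix(FALSE, n, k))
      run <- run & shifted
    }
  }
  started_inside <- run[, 1]
  run[started_inside, ] <- FALSE
  hit <- which(run, arr.ind = TRUE)
  if (!nrow(hit)) {
    return(tibble(x_mm = numeric(0), y_mm = numeric(0), z_mm = numeric(0),
                  ray = integer(0), depth_mm = numeric(0),
                  offending = integer(0), participation = integer(0),
                  valid = logical(0)))
  }
  o <- order(hit[, 1], hit[, 2])
  hit <- hit[o, , drop = FALSE]
  first <- hit[!duplicated(hit[, 1]), , drop = FALSE]
  t_hit <- tvals[first[, 2]]
  ray <- first[, 1]
  # sub-step refinement: place the surface point at the linear threshold
  # crossing between the last below-threshold sample and the first sample of
  # the qualifying run, removing the half-step inward bias of the raw rule
  j <- first[, 2]
  can <- j > 1L
  if (any(can)) {
    vmat <- matrix(vals, n, n_steps)
    v1 <- vmat[cbind(ray[can], j[can])]
    v0 <- vmat[cbind(ray[can], j[can] - 1L)]
    frac <- (threshold - v0) / (v1 - v0)
    good <- is.finite(frac) & v0 < threshold & frac >= 0 & frac <= 1
    t_hit[can][good] <- tvals[j[can] - 1L][good] + step * frac[good]
  }
  tibble(
    x_mm = starts[ray, 1] + dirs[ray, 1] * t_hit,
    y_mm = starts[ray, 2] + dirs[ray, 2] * t_hit,
    z_mm = starts[ray, 3] + dirs[ray, 3] * t_hit,
    ray = as.integer(ray),
    depth_mm = t_hit,
    offending = 0L,
    participation = 0L,
    valid = TRUE)
}

default_step <- function(vol, cfg) {
  if (!is.null(cfg$step_size)) cfg$step_size else min(vol$spacing) / 2
}

check_threshold <- function(vol, cfg) {
  rng <- range(vol$data)
  if (cfg$threshold >= rng[2]) {
    stop_hipwear(
      sprintf("threshold %g is at or above the volume maximum %g; no surface can be found",
              cfg$threshold, rng[2]),
      "hipwear_empty_surface")
  }
}

#' Extract candidate points on the outer cup surface
#'
#' Rays are cast inward toward the estimated cup center (the apical point
#' projected onto the rim plane) from outside the starting radius, over
#' Fibonacci-spiral directions on the hemisphere on the apex side of the rim
#' plane. Each ray reports the first position whose intensity exceeds the
#' threshold for `min_run_length` consecutive samples; travel is capped at
#' `cup_range_fraction` times the starting radius so rays passing through
#' unused screw holes stop before reaching interior structures.
#'
#' @param vol A [ct_volume()].
#' @param lm A `landmark_set`.
#' @param cfg An [extraction_config()].
#' @return A surface-point tibble with columns `x_mm`, `y_mm`, `z_mm`,
#'   `ray`, `depth_mm`, `offending`, `participation`, `valid`.
#' @export
extract_cup_surface <- function(vol, lm, cfg) {
  lm <- as_landmark_set(lm)
  check_threshold(vol, cfg)
  plane <- fit_plane(lm_point(lm, "rim1"), lm_point(lm, "rim2"),
                     lm_point(lm, "rim3"))
  apex <- lm_point(lm, if (cfg$radius_landmark == "apex") "apex" else "cup_offset")
  # orient the plane normal toward the apex side
  if (sum((apex - plane$point) * plane$normal) < 0) {
    plane$normal <- -plane$normal
  }
  r_start <- starting_radius(plane, apex)
  center_est <- apex - sum((apex - plane$point) * plane$normal) * plane$normal
  dirs_out <- fibonacci_directions(cfg$n_ray_directions, hemisphere = TRUE,
                                   axis = plane$normal)
  # skip rays whose surface hit would land within rim_margin_mm of the rim
  # plane, where the hemispherical shell is cut off
  elev <- as.numeric(dirs_out %*% plane$normal)
  dirs_out <- dirs_out[elev * r_start >= cfg$rim_margin_mm, , drop = FALSE]
  starts <- sweep(1.2 * r_start * dirs_out, 2, center_est, "+")
  step <- default_step(vol, cfg)
  pts <- cast_rays(vol, starts, -dirs_out,
                   max_travel = cfg$cup_range_fraction * r_start,
                   step = step, threshold = cfg$threshold,
                   min_run_length = cfg$min_run_length)
  if (!nrow(pts)) {
    stop_hipwear("no cup surface points found; check threshold and landmarks",
                 "hipwear_empty_surface")
  }
  pts
}

#' Extract candidate points on the femoral head surface
#'
#' Rays are cast inward from the head-enclosing landmark sphere toward its
#' center with the same run-length crossing rule. Rays whose path intersects
#' the stem-junction landmark sphere are discarded, which keeps the search
#' from extending onto the stem; rays that start inside metal are discarded
#' as well.
#'
#' @inheritParams extract_cup_surface
#' @return A surface-point tibble (see [extract_cup_surface()]).
#' @export
extract_head_surface <- function(vol, lm, cfg) {
  lm <- as_landmark_set(lm)
  check_threshold(vol, cfg)
  enc <- lm_sphere(lm, "head_enclosing")
  stem <- lm_sphere(lm, "stem_junction")
  dirs_out <- fibonacci_directions(cfg$n_ray_directions, hemisphere = FALSE)
  starts <- sweep(enc$radius * dirs_out, 2, enc$center, "+")
  # discard rays whose segment (start -> enclosing center) meets the stem
  # sphere: these would otherwise land on the stem, not the head
  w <- sweep(starts, 2, stem$center, "-")
  b <- rowSums(w * (-dirs_out))
  disc <- b^2 - (rowSums(w^2) - stem$radius^2)
  t1 <- -b - sqrt(pmax(disc, 0))
  t2 <- -b + sqrt(pmax(disc, 0))
  hits_stem <- disc > 0 & t2 > 0 & t1 < enc$radius
  keep <- !hits_stem
  if (!any(keep)) {
    stop_hipwear("all head rays intersect the stem landmark sphere",
                 "hipwear_empty_surface")
  }
  step <- default_step(vol, cfg)
  pts <- cast_rays(vol, starts[keep, , drop = FALSE],
                   -dirs_out[keep, , drop = FALSE],
                   max_travel = enc$radius, step = step,
                   threshold = cfg$threshold,
                   min_run_length = cfg$min_run_length)
  if (!nrow(pts)) {
    stop_hipwear("no head surface points found; check threshold and landmarks",
                 "hipwear_empty_surface")
  }
  if (nrow(pts) < 500) {
    warn(sprintf(paste("only %d head surface points found; the enclosing",
                       "landmark may be too small or misplaced"), nrow(pts)),
         class = "hipwear_sparse_surface")
  }
  pts
}

#' Write surface points to CSV (for inspection)
#'
#' @param pts A surface-point tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_surface_points <- function(pts, path) {
  readr::write_csv(pts, path)
  invisible(path)
}
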