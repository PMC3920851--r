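# Synthetic CT phantom of a cup + head + stem assembly with known ground
# truth, emulating a micrometer rig that translates the head relative to the
# cup by sub-voxel amounts between scans.

#' Specify a synthetic hip phantom
#'
#' Defaults describe the reference phantom: a 54.2 mm hemispherical metal
#' shell (acetabular cup) with an apical dome hole, a solid 22.1 mm head on a
#' cylindrical stem, imaged at 0.2 mm isotropic voxels with a Gaussian
#' point-spread function and additive noise. The cup center sits at the world
#' origin with the cup axis along +z and the opening facing -z; the head
#' center coincides with the cup center at the reference position so that a
#' head displacement translates directly into a cup-head center separation.
#'
#' @param cup_outer_diameter Outer diameter of the cup shell, mm.
#' @param cup_shell_thickness Shell thickness, mm.
#' @param dome_hole_diameter Diameter of the apical dome hole, mm.
#' @param screw_hole_diameters Diameters of unused screw holes, mm (radial
#'   cylindrical holes at 45 degrees latitude); empty for none.
#' @param head_diameter Head diameter, mm.
#' @param stem_radius Stem cylinder radius, mm.
#' @param stem_axis Unit vector of the stem direction from the head center.
#' @param head_center_offset Head center relative to the cup center, mm.
#' @param metal_intensity,background_intensity Intensities in arbitrary
#'   units; any extraction threshold must lie strictly between them.
#' @param roughness_amplitude Amplitude (mm) of a band-limited radial
#'   perturbation of the outer cup surface emulating a trabecular coating;
#'   0 disables it.
#' @param psf_sigma Gaussian PSF sigma in mm (partial-volume blur).
#' @param noise_sd Additive Gaussian noise SD, intensity units.
#' @param voxel_spacing Length-3 voxel spacing, mm.
#' @param grid_shape Length-3 voxel counts. The default comfortably contains
#'   the default implant; [generate_phantom()] errors if it does not.
#' @param rng_seed Integer seed controlling noise and roughness.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(cup_outer_diameter = 54.2,
                         cup_shell_thickness = 4,
                         dome_hole_diameter = 8,
                         screw_hole_diameters = numeric(0),
                         head_diameter = 22.1,
                         stem_radius = 6,
                         stem_axis = c(0, 0, -1),
                         head_center_offset = c(0, 0, 0),
                         metal_intensity = 3000,
                         background_intensity = 0,
                         roughness_amplitude = 0,
                         psf_sigma = 0.2,
                         noise_sd = 150,
                         voxel_spacing = c(0.2, 0.2, 0.2),
                         grid_shape = c(288, 288, 244),
                         rng_seed = 1L) {
  spec <- list(
    cup_outer_diameter = cup_outer_diameter,
    cup_shell_thickness = cup_shell_thickness,
    dome_hole_diameter = dome_hole_diameter,
    screw_hole_diameters = as.numeric(screw_hole_diameters),
    head_diameter = head_diameter,
    stem_radius = stem_radius,
    stem_axis = as.numeric(stem_axis) / sqrt(sum(stem_axis^2)),
    head_center_offset = as.numeric(head_center_offset),
    metal_intensity = metal_intensity,
    background_intensity = background_intensity,
    roughness_amplitude = roughness_amplitude,
    psf_sigma = psf_sigma,
    noise_sd = noise_sd,
    voxel_spacing = as.numeric(voxel_spacing),
    grid_shape = as.integer(grid_shape),
    rng_seed = as.integer(rng_seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(spec) {
  if (!(spec$cup_outer_diameter > spec$head_diameter &&
        spec$head_diameter > 0)) {
    stop_hipwear("need cup_outer_diameter > head_diameter > 0",
                 "hipwear_configuration_error")
  }
  if (any(spec$voxel_spacing <= 0) || any(spec$grid_shape < 8L)) {
    stop_hipwear("voxel spacing must be positive and the grid nondegenerate",
                 "hipwear_configuration_error")
  }
  if (spec$metal_intensity <= spec$background_intensity) {
    stop_hipwear("metal_intensity must exceed background_intensity",
                 "hipwear_configuration_error")
  }
  if (spec$cup_shell_thickness <= 0 ||
      spec$cup_shell_thickness >= spec$cup_outer_diameter / 2) {
    stop_hipwear("cup_shell_thickness must be positive and below the cup radius",
                 "hipwear_configuration_error")
  }
  invisible(spec)
}

# Grid placement: x and y are centered on the cup center (world origin); the
# top grid face sits a fixed 1.5 mm margin above the cup dome, leaving the
# space below for head and stem.
phantom_origin <- function(spec) {
  n <- spec$grid_shape; s <- spec$voxel_spacing
  r_out <- spec$cup_outer_diameter / 2
  zmax <- r_out + 1.5
  c(-(n[1] - 1) * s[1] / 2, -(n[2] - 1) * s[2] / 2, zmax - (n[3] - 1) * s[3])
}

#' Generate a synthetic phantom volume with ground truth
#'
#' Voxels inside the cup shell (outer hemisphere minus dome and screw holes)
#' and inside the head and stem receive `metal_intensity`; the volume is then
#' blurred with a Gaussian PSF (partial-volume emulation) and corrupted with
#' additive Gaussian noise. Fully deterministic given `spec$rng_seed`.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `volume` (a [ct_volume()]) and `truth`
#'   (class `ground_truth`: `cup_sphere`, `head_sphere` \[[sphere_model()]\]
#'   and the `displacement` triple, taken as `head_center_offset`).
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  n <- spec$grid_shape; s <- spec$voxel_spacing
  origin <- phantom_origin(spec)
  r_out <- spec$cup_outer_diameter / 2
  r_in <- r_out - spec$cup_shell_thickness
  r_head <- spec$head_diameter / 2
  margin <- 3 * spec$psf_sigma + max(s)
  ext_lo <- origin
  ext_hi <- origin + (n - 1) * s
  h <- spec$head_center_offset
  if (r_out + margin > min(ext_hi[1], -ext_lo[1], ext_hi[2], -ext_lo[2],
                           ext_hi[3]) ||
      h[3] - r_head - margin < ext_lo[3] ||
      any(abs(h[1:2]) + r_head + margin > ext_hi[1:2])) {
    stop_hipwear("implant does not fit inside the grid with margin",
                 "hipwear_configuration_error")
  }

  xs <- origin[1] + (seq_len(n[1]) - 1) * s[1]
  ys <- origin[2] + (seq_len(n[2]) - 1) * s[2]
  zs <- origin[3] + (seq_len(n[3]) - 1) * s[3]
  nvox <- prod(n)
  X2 <- rep(xs^2, times = n[2] * n[3])
  Y2 <- rep(rep(ys^2, each = n[1]), times = n[3])
  rho2 <- X2 + Y2
  r2 <- rho2 + rep(zs^2, each = n[1] * n[2])
  Z <- rep(zs, each = n[1] * n[2])

  withr::with_seed(spec$rng_seed, {
    # outer cup radius, optionally perturbed per direction by band-limited
    # roughness (trabecular-coating emulation)
    if (spec$roughness_amplitude > 0) {
      r_surface <- r_out + roughness_field(sqrt(r2), X2, Y2, Z, spec)
    } else {
      r_surface <- r_out
    }
    shell <- r2 <= r_surface^2 & r2 >= r_in^2 & Z >= 0 &
      rho2 > (spec$dome_hole_diameter / 2)^2
    if (length(spec$screw_hole_diameters)) {
      X <- rep(xs, times = n[2] * n[3])
      Y <- rep(rep(ys, each = n[1]), times = n[3])
      for (i in seq_along(spec$screw_hole_diameters)) {
        u <- screw_hole_axis(i)
        along <- X * u[1] + Y * u[2] + Z * u[3]
        perp2 <- pmax(r2 - along^2, 0)
        shell <- shell &
          !(along > 0 & perp2 < (spec$screw_hole_diameters[i] / 2)^2)
      }
      rm(X, Y)
    }
    hr2 <- rep((xs - h[1])^2, times = n[2] * n[3]) +
      rep(rep((ys - h[2])^2, each = n[1]), times = n[3]) +
      rep((zs - h[3])^2, each = n[1] * n[2])
    head <- hr2 <= r_head^2
    # stem: cylinder from the head center along stem_axis to the grid edge
    u <- spec$stem_axis
    X <- rep(xs, times = n[2] * n[3]) - h[1]
    Y <- rep(rep(ys, each = n[1]), times = n[3]) - h[2]
    Zh <- Z - h[3]
    along <- X * u[1] + Y * u[2] + Zh * u[3]
    perp2 <- pmax(X^2 + Y^2 + Zh^2 - along^2, 0)
    stem <- along > 0 & perp2 <= spec$stem_radius^2
    rm(X, Y, Zh, r2, rho2, X2, Y2, hr2)

    vol <- spec$background_intensity +
      (spec$metal_intensity - spec$background_intensity) *
      as.numeric(shell | head | stem)
    rm(shell, head, stem)

    arr <- array(vol, dim = n)
    rm(vol)
    if (spec$psf_sigma > 0) {
      arr <- gaussian_blur3(arr, spec$voxel_spacing, spec$psf_sigma)
    }
    if (spec$noise_sd > 0) {
      arr <- arr + rnorm(nvox, 0, spec$noise_sd)
    }
  })

  truth <- structure(
    list(cup_sphere = sphere_model(c(0, 0, 0), r_out),
         head_sphere = sphere_model(h, r_head),
         displacement = h),
    class = "ground_truth")
  list(volume = ct_volume(arr, spacing = s, origin = origin), truth = truth)
}

# Fixed screw-hole directions: 45 degrees latitude, golden-angle azimuths.
screw_hole_axis <- function(i) {
  az <- (i - 1) * 2.39996322972865332
  c(cos(az) * cos(pi / 4), sin(az) * cos(pi / 4), sin(pi / 4))
}

# Band-limited radial roughness: a smoothed Gaussian field on a coarse 3-D
# lattice over the unit ball, evaluated at each voxel's unit direction and
# scaled to the requested amplitude (values clamped to +/- amplitude).
# Only voxels near the outer surface are evaluated.
roughness_field <- function(r, X2, Y2, Z, spec) {
  amp <- spec$roughness_amplitude
  ng <- 9L
  g <- array(rnorm(ng^3), c(ng, ng, ng))
  k <- c(0.25, 0.5, 0.25)
  sm1 <- function(a, d) {
    a <- aperm(a, switch(d, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 2, 1)))
    m <- matrix(a, dim(a)[1])
    m <- k[1] * rbind(m[1, ], m[-dim(a)[1], ]) + k[2] * m +
      k[3] * rbind(m[-1, ], m[dim(a)[1], ])
    a <- array(m, dim(a))
    aperm(a, switch(d, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 2, 1)))
  }
  for (d in 1:3) g <- sm1(g, d)
  g <- g / stats::sd(g) * (amp / 2)
  g <- pmin(pmax(g, -amp), amp)
  gv <- ct_volume(g, spacing = rep(2 / (ng - 1), 3), origin = rep(-1, 3))
  delta <- numeric(length(r))
  near <- abs(r - spec$cup_outer_diameter / 2) <= 2 * amp + 0.5
  if (any(near)) {
    rn <- pmax(r[near], 1e-9)
    # quadrant-symmetric evaluation (|x|, |y|): adequate for an arbitrary
    # perturbation field and avoids carrying signed coordinate vectors
    pts <- cbind(sqrt(X2[near]) / rn, sqrt(Y2[near]) / rn, Z[near] / rn)
    delta[near] <- interp_trilinear(gv, pts, outside = 0)
  }
  delta
}

# Separable Gaussian blur in world units via sparse band-matrix products.
gaussian_blur3 <- function(arr, spacing, sigma) {
  d <- dim(arr)
  for (ax in 1:3) {
    rad <- max(1L, as.integer(ceiling(4 * sigma / spacing[ax])))
    k <- dnorm((-rad:rad) * spacing[ax], 0, sigma)
    k <- k / sum(k)
    M <- Matrix::bandSparse(
      d[ax], d[ax], k = -rad:rad,
      diagonals = lapply(-rad:rad, function(off) rep(k[off + rad + 1],
                                                     d[ax] - abs(off))))
    perm <- switch(ax, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    inv <- switch(ax, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(2, 3, 1))
    a <- aperm(arr, perm)
    dp <- dim(a)
    a <- array(as.matrix(M %*% matrix(a, dp[1])), dp)
    arr <- aperm(a, inv)
  }
  arr
}

#' Generate a displacement series of phantoms
#'
#' One volume per displacement triple, sharing the base geometry; scan i uses
#' seed `base rng_seed + i` so noise realisations are independent but
#' reproducible. The first displacement is conventionally `(0, 0, 0)`, the
#' reference scan.
#'
#' @param base_spec A [phantom_spec()]; its `head_center_offset` is the
#'   baseline to which each displacement is added.
#' @param displacements A list of length-3 numeric triples, or a 3-column
#'   matrix / data frame of `dx, dy, dz` in mm.
#' @return A list of `list(volume, truth)` pairs, one per displacement.
#' @export
generate_series <- function(base_spec, displacements) {
  displacements <- as_displacement_list(displacements)
  if (!length(displacements)) {
    stop_hipwear("displacement list must be nonempty",
                 "hipwear_configuration_error")
  }
  purrr::imap(displacements, function(d, i) {
    generate_phantom(series_spec(base_spec, d, i))
  })
}

# Spec for scan i of a series: baseline offset + displacement, derived seed.
series_spec <- function(base_spec, d, i) {
  spec <- base_spec
  spec$head_center_offset <- base_spec$head_center_offset + as.numeric(d)
  spec$rng_seed <- base_spec$rng_seed + as.integer(i)
  class(spec) <- "phantom_spec"
  spec
}

as_displacement_list <- function(displacements) {
  if (is.data.frame(displacements)) {
    displacements <- as.matrix(displacements[, c("dx", "dy", "dz")])
  }
  if (is.matrix(displacements)) {
    displacements <- lapply(seq_len(nrow(displacements)),
                            function(i) as.numeric(displacements[i, ]))
  }
  lapply(displacements, function(d) as_point3(d, "displacement"))
}

#' Micrometer displacement design of the phantom experiment
#'
#' The 14 head displacements (mm) applied between scans, with the scan
#' letters of the two acquisition series, and the expected cup-head center
#' separation implied by each triple. The first row is the zero-displacement
#' reference.
#'
#' @return A tibble with columns `scan_one`, `scan_two`, `dx`, `dy`, `dz`,
#'   `expected` (mm).
#' @export
table1_displacements <- function() {
  d <- tibble::tribble(
    ~scan_one, ~scan_two,   ~dx,   ~dy,   ~dz,
    "T", "A", 0.000, 0.000, 0.000,
    "K", "G", 0.000, 0.000, 0.000,
    "X", "T", 0.050, 0.050, 0.050,
    "W", "F", 0.100, 0.100, 0.100,
    "N", "R", 0.150, 0.100, 0.100,
    "P", "M", 0.150, 0.150, 0.100,
    "A", "Y", 0.150, 0.150, 0.150,
    "R", "D", 0.200, 0.200, 0.200,
    "H", "W", 0.250, 0.250, 0.250,
    "Z", "C", 0.300, 0.300, 0.300,
    "D", "K", 0.350, 0.350, 0.350,
    "M", "P", 0.400, 0.400, 0.400,
    "E", "V", 0.450, 0.450, 0.450,
    "S", "Z", 0.500, 0.500, 0.500)
  d$expected <- expected_separation(d$dx, d$dy, d$dz)
  d
}

#' Place the seven operator landmarks automatically from ground truth
#'
#' Stands in for the human operator on synthetic data: three rim points on
#' the cup's equatorial plane, an apical point centered in the dome hole, an
#' offset point a short distance outward along the cup axis, a spherical
#' landmark at the head-stem junction, and a spherical landmark enclosing
#' the whole head.
#'
#' @param truth A `ground_truth` from [generate_phantom()].
#' @param spec The [phantom_spec()] that produced it.
#' @param offset_distance Distance (mm) of the offset point beyond the apex
#'   along the cup axis (operator protocol: 5-10 mm).
#' @param enclosing_margin Head-enclosing sphere radius margin beyond the
#'   head radius, mm; must be at least 2 voxels.
#' @return A landmark tibble (see [as_landmark_set()]).
#' @export
auto_landmarks <- function(truth, spec, offset_distance = 7.5,
                           enclosing_margin = 2) {
  r_out <- truth$cup_sphere$radius
  cc <- truth$cup_sphere$center
  hc <- truth$head_sphere$center
  r_head <- truth$head_sphere$radius
  enclosing_margin <- max(enclosing_margin, 2 * max(spec$voxel_spacing))
  rim <- lapply(c(0, 2 * pi / 3, 4 * pi / 3), function(a) {
    cc + r_out * c(cos(a), sin(a), 0)
  })
  apex <- cc + c(0, 0, r_out)
  offs <- apex + c(0, 0, offset_distance)
  junction <- hc + spec$stem_axis * r_head
  lm <- tibble::tibble(
    name = c("rim1", "rim2", "rim3", "apex", "cup_offset",
             "stem_junction", "head_enclosing"),
    x_mm = c(rim[[1]][1], rim[[2]][1], rim[[3]][1], apex[1], offs[1],
             junction[1], hc[1]),
    y_mm = c(rim[[1]][2], rim[[2]][2], rim[[3]][2], apex[2], offs[2],
             junction[2], hc[2]),
    z_mm = c(rim[[1]][3], rim[[2]][3], rim[[3]][3], apex[3], offs[3],
             junction[3], hc[3]),
    # junction sphere must not reach the head center, or it would occlude
    # every inward ray of the head search
    radius_mm = c(NA, NA, NA, NA, NA,
                  min(spec$stem_radius + 2, 0.9 * r_head),
                  r_head + enclosing_margin))
  as_landmark_set(lm)
}
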