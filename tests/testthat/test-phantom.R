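test_that("phantom generation is deterministic given the seed", {
  spec <- small_phantom_spec(grid_shape = c(64, 64, 56),
                             cup_outer_diameter = 10, cup_shell_thickness = 2,
                             dome_hole_diameter = 2, head_diameter = 4.5,
                             stem_radius = 1.2)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth, b$truth)
  spec2 <- spec; spec2$rng_seed <- spec$rng_seed + 1L
  c <- generate_phantom(spec2)
  expect_false(identical(a$volume$data, c$volume$data))
})

test_that("ground truth reflects the spec and displacement norm exactly", {
  for (seed in 1:10) {
    d <- withr::with_seed(seed, runif(3, -0.5, 0.5))
    spec <- small_phantom_spec(head_center_offset = d, noise_sd = 0,
                               psf_sigma = 0)
    spec$grid_shape <- c(48L, 48L, 40L)  # truth does not need the voxel grid
    spec$cup_outer_diameter <- 8; spec$head_diameter <- 3
    spec$cup_shell_thickness <- 1.5; spec$dome_hole_diameter <- 1.5
    spec$stem_radius <- 0.8
    ph <- generate_phantom(spec)
    expect_identical(ph$truth$displacement, as.numeric(d))
    expect_equal(cup_head_separation(ph$truth$cup_sphere,
                                     ph$truth$head_sphere),
                 sqrt(sum(d^2)), tolerance = 1e-12)
    expect_equal(ph$truth$cup_sphere$radius, spec$cup_outer_diameter / 2)
    expect_equal(ph$truth$head_sphere$radius, spec$head_diameter / 2)
  }
})

test_that("an implant that exceeds the grid is a configuration error", {
  spec <- small_phantom_spec()
  spec$grid_shape <- c(64L, 64L, 64L)  # 12.8 mm extent cannot hold a 20 mm cup
  expect_error(generate_phantom(spec), class = "hipwear_configuration_error")
})

test_that("noiseless blur-free surface voxels lie on the analytic sphere", {
  spec <- small_phantom_spec(noise_sd = 0, psf_sigma = 0)
  ph <- generate_phantom(spec)
  thr <- (spec$metal_intensity + spec$background_intensity) / 2
  metal <- ph$volume$data > thr
  d <- dim(metal)
  # boundary voxels: metal with at least one non-metal 6-neighbour
  shift <- function(m, ax, by) {
    idx <- lapply(d, seq_len)
    idx[[ax]] <- pmin(pmax(idx[[ax]] + by, 1L), d[ax])
    m[idx[[1]], idx[[2]], idx[[3]]]
  }
  interior <- metal
  for (ax in 1:3) for (by in c(-1L, 1L)) {
    interior <- interior & shift(metal, ax, by)
  }
  boundary <- which(metal & !interior, arr.ind = TRUE)
  xyz <- sweep(sweep(boundary - 1, 2, ph$volume$spacing, "*"), 2,
               ph$volume$origin, "+")
  r <- sqrt(rowSums(xyz^2))
  rho <- sqrt(xyz[, 1]^2 + xyz[, 2]^2)
  r_out <- spec$cup_outer_diameter / 2
  r_in <- r_out - spec$cup_shell_thickness
  # outer cup hemisphere only: away from the rim cut, the dome hole and the
  # inner surface
  keep <- xyz[, 3] > 0.5 & r > (r_in + r_out) / 2 &
    rho > spec$dome_hole_diameter / 2 + 1
  expect_gt(sum(keep), 1000)
  # a face-connected boundary voxel can sit at most one voxel step inside
  # the surface; the typical deviation is well under half the voxel diagonal
  half_diag <- sqrt(sum(ph$volume$spacing^2)) / 2
  expect_lt(max(abs(r[keep] - r_out)), max(ph$volume$spacing) + 1e-12)
  expect_lt(stats::quantile(abs(r[keep] - r_out), 0.95), half_diag)
})

test_that("a series shares geometry and matches the displacement design", {
  spec <- small_phantom_spec(grid_shape = c(64, 64, 56),
                             cup_outer_diameter = 10, cup_shell_thickness = 2,
                             dome_hole_diameter = 2, head_diameter = 4.5,
                             stem_radius = 1.2)
  design <- table1_displacements()
  series <- generate_series(spec, design[, c("dx", "dy", "dz")])
  expect_length(series, 14)
  seps <- vapply(series, function(s) {
    cup_head_separation(s$truth$cup_sphere, s$truth$head_sphere)
  }, 0)
  # note |(0.4, 0.4, 0.4)| = 0.69282 rounds to 0.693
  expect_equal(round(seps, 3),
               c(0, 0, 0.087, 0.173, 0.206, 0.235, 0.260, 0.346, 0.433,
                 0.520, 0.606, 0.693, 0.779, 0.866))
  expect_equal(seps[1], 0)
  cups <- t(vapply(series, function(s) s$truth$cup_sphere$center, double(3)))
  expect_true(all(cups == 0))  # cup fixed; only the head moves

  single <- generate_series(spec, list(c(0.1, 0, 0)))
  expect_equal(single[[1]]$truth$displacement, c(0.1, 0, 0))
  expect_equal(cup_head_separation(single[[1]]$truth$cup_sphere,
                                   single[[1]]$truth$head_sphere), 0.1)
})

test_that("automatic landmarks satisfy the seven-landmark protocol", {
  spec <- small_phantom_spec(noise_sd = 0)
  ph <- generate_phantom(spec)
  lm <- auto_landmarks(ph$truth, spec)
  expect_s3_class(lm, "landmark_set")
  expect_equal(nrow(lm), 7)
  rim <- as.matrix(lm[1:3, c("x_mm", "y_mm", "z_mm")])
  expect_no_error(fit_plane(rim[1, ], rim[2, ], rim[3, ]))
  # head-enclosing sphere contains the whole ground-truth head sphere
  enc <- lm[lm$name == "head_enclosing", ]
  gap <- sqrt(sum((c(enc$x_mm, enc$y_mm, enc$z_mm) -
                     ph$truth$head_sphere$center)^2))
  expect_gte(enc$radius_mm, gap + ph$truth$head_sphere$radius)
  # offset point is 5-10 mm outward of the apex along the cup axis
  d_apex <- sqrt(sum((as.numeric(lm[lm$name == "cup_offset", 2:4]) -
                        as.numeric(lm[lm$name == "apex", 2:4]))^2))
  expect_gte(d_apex, 5); expect_lte(d_apex, 10)
})

test_that("roughness perturbs the outer surface within its amplitude", {
  spec0 <- small_phantom_spec(noise_sd = 0, psf_sigma = 0)
  spec1 <- small_phantom_spec(noise_sd = 0, psf_sigma = 0,
                              roughness_amplitude = 0.3)
  pha <- generate_phantom(spec0)
  a <- pha$volume$data
  b <- generate_phantom(spec1)$volume$data
  changed <- which(a != b, arr.ind = TRUE)
  expect_gt(nrow(changed), 0)
  xyz <- sweep(sweep(changed - 1, 2, spec0$voxel_spacing, "*"), 2,
               pha$volume$origin, "+")
  r <- sqrt(rowSums(xyz^2))
  # changes are confined to a band around the outer cup surface
  expect_true(all(abs(r - spec0$cup_outer_diameter / 2) <
                    0.3 + sqrt(sum(spec0$voxel_spacing^2))))
})
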