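test_that("quadruple sampling honours separation, count and determinism", {
  pts <- sphere_points(1000, c(0, 0, 0), 15, seed = 3)
  cfg <- fit_config(n_samples = 100, rng_seed = 42)
  q <- sample_quadruples(pts, cfg)
  expect_equal(dim(q), c(100, 4))
  for (a in 1:3) for (b in (a + 1):4) {
    d <- sqrt(rowSums((pts[q[, a], ] - pts[q[, b], ])^2))
    expect_true(all(d >= cfg$min_pair_separation))
  }
  expect_identical(q, sample_quadruples(pts, cfg))
  expect_false(identical(q, sample_quadruples(pts, cfg, seed = 43)))
})

test_that("tightly clustered points cannot seed quadruples", {
  pts <- sphere_points(100, c(0, 0, 0), 0.4, seed = 1)  # inside a 1 mm ball
  expect_error(sample_quadruples(pts, fit_config(n_samples = 10)),
               class = "hipwear_insufficient_points")
})

test_that("the radius histogram initialises at the true radius", {
  cfg <- fit_config(n_samples = 20000, rng_seed = 7)
  bw <- diff(cfg$histogram_range) / cfg$n_histogram_bins

  full <- sphere_points(2000, c(2, -1, 3), 11.05, seed = 11)
  est <- initial_radius_estimate(full, cfg)
  expect_lt(abs(est$initial_radius - 11.05), bw)
  expect_equal(est$initial_center, c(2, -1, 3), tolerance = 0.05,
               ignore_attr = TRUE)

  hemi <- sphere_points(2000, c(0, 0, 0), 27.1, seed = 12, hemisphere = TRUE)
  est <- initial_radius_estimate(hemi, cfg)
  expect_lt(abs(est$initial_radius - 27.1), bw)

  # 10% gross outliers on a larger shell do not move the maximal bin
  good <- sphere_points(1800, c(0, 0, 0), 27.105, seed = 13)
  bad <- sphere_points(200, c(0, 0, 0), 40, seed = 14)
  est <- initial_radius_estimate(rbind(good, bad), cfg)
  expect_lt(abs(est$initial_radius - 27.105), 2 * bw)
})

test_that("pruning removes offending points and only those", {
  cfg <- fit_config(n_samples = 30000, rng_seed = 5)

  clean <- hipwear:::as_surface_points(
    sphere_points(3000, c(0, 0, 0), 27.1, seed = 21, noise_sd = 0.02))
  pruned <- prune_landmarks(clean, 27.1, cfg$coarse_tolerance, cfg)
  expect_equal(sum(pruned$valid), nrow(clean))

  # cup-like analogue: ~15,000 points with dome-hole-edge contamination
  inl <- sphere_points(12750, c(0, 0, 0), 27.1, seed = 22,
                       hemisphere = TRUE, noise_sd = 0.03)
  edge <- withr::with_seed(23, {
    phi <- runif(2250, 0, 2 * pi)
    depth <- runif(2250, 0, 4)   # down the cylindrical hole wall
    r <- sqrt(27.1^2 - 4^2) - depth
    cbind(4 * cos(phi), 4 * sin(phi), r)
  })
  cup_like <- hipwear:::as_surface_points(rbind(inl, edge))
  cfg_cup <- fit_config(n_samples = 80000, rng_seed = 6)
  pr <- prune_landmarks(cup_like, 27.1, cfg_cup$coarse_tolerance, cfg_cup)
  pr <- prune_landmarks(pr, 27.1, cfg_cup$fine_tolerance, cfg_cup,
                        seed = 7)
  expect_gte(sum(pr$valid), 12500)
  expect_lte(sum(pr$valid), 13000)
  # pruning hits the contaminated tail, not the inliers
  expect_gt(mean(!pr$valid[12751:15000]), 0.8)
  expect_gt(mean(pr$valid[1:12750]), 0.97)

  # head-like analogue: 2,000 points with gross contamination
  h_in <- sphere_points(1600, c(0, 0, 0), 11.05, seed = 24, noise_sd = 0.03)
  h_out <- sphere_points(400, c(0, 0, 0), 13.5, seed = 25)
  head_like <- hipwear:::as_surface_points(rbind(h_in, h_out))
  pr2 <- prune_landmarks(head_like, 11.05, 0.4, fit_config(rng_seed = 8))
  expect_gt(mean(!pr2$valid[1601:2000]), 0.9)
  expect_gt(mean(pr2$valid[1:1600]), 0.95)

  expect_error(
    prune_landmarks(hipwear:::as_surface_points(
      sphere_points(500, c(0, 0, 0), 30, seed = 26)),
      10, 0.1, fit_config(n_samples = 5000, rng_seed = 9)),
    class = "hipwear_fitting_error")
})

test_that("pruning is monotone across passes", {
  pts <- hipwear:::as_surface_points(rbind(
    sphere_points(2000, c(0, 0, 0), 20, seed = 31, noise_sd = 0.05),
    sphere_points(300, c(0, 0, 0), 24, seed = 32)))
  cfg <- fit_config(n_samples = 20000, rng_seed = 3)
  p1 <- prune_landmarks(pts, 20, cfg$coarse_tolerance, cfg, seed = 4)
  p2 <- prune_landmarks(p1, 20, cfg$fine_tolerance, cfg, seed = 5)
  expect_true(all(which(p1$valid) %in% which(pts$valid)))
  expect_true(all(which(p2$valid) %in% which(p1$valid)))
})

test_that("geometric least squares is exact, unbiased and robust to partial coverage", {
  p4 <- sphere_points(4, c(1, 2, 3), 9, seed = 41)
  ls <- least_squares_sphere(p4)
  cs <- circumsphere(p4[1, ], p4[2, ], p4[3, ], p4[4, ])
  expect_equal(ls$center, cs$center, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(ls$radius, cs$radius, tolerance = 1e-8)

  expect_error(least_squares_sphere(cbind(matrix(rnorm(20), 10), 0)),
               class = "hipwear_degenerate_geometry")

  # Monte-Carlo: radius bias under radial noise
  rad <- vapply(1:200, function(s) {
    least_squares_sphere(sphere_points(2000, c(0, 0, 0), 27.105, seed = s,
                                       noise_sd = 0.05))$radius
  }, 0)
  expect_lt(abs(mean(rad) - 27.105), 0.005)

  # hemisphere-only coverage still recovers the center
  cerr <- vapply(1:30, function(s) {
    f <- least_squares_sphere(sphere_points(2000, c(5, -2, 1), 27.1,
                                            seed = 400 + s,
                                            hemisphere = TRUE,
                                            noise_sd = 0.05))
    sqrt(sum((f$center - c(5, -2, 1))^2))
  }, 0)
  expect_lt(mean(cerr), 0.01)
})

test_that("the full robust fit recovers exact spheres to machine precision", {
  pts <- sphere_points(5000, c(10, -3, 44), 27.105, seed = 51)
  fit <- fit_sphere(pts, fit_config(n_samples = 20000, rng_seed = 2))
  expect_equal(fit$center, c(10, -3, 44), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(fit$radius, 27.105, tolerance = 1e-6)
  expect_equal(fit$n_valid_points, 5000)
  g <- glance(fit)
  expect_equal(g$diameter, 2 * fit$radius)
  expect_equal(tidy(fit)$estimate[4], fit$radius)
})

test_that("the fit is translation-equivariant and rotation-invariant in radius", {
  pts <- sphere_points(1500, c(0, 0, 0), 14, seed = 61, hemisphere = TRUE,
                       noise_sd = 0.05)
  cfg <- fit_config(n_samples = 10000, rng_seed = 77)
  base <- fit_sphere(pts, cfg)
  t <- c(3.5, -8, 12)
  shifted <- fit_sphere(sweep(pts, 2, t, "+"), cfg)
  expect_equal(shifted$center, base$center + t, tolerance = 1e-9)
  expect_equal(shifted$radius, base$radius, tolerance = 1e-9)
  R <- random_rotation(62)
  rotated <- fit_sphere(pts %*% t(R), cfg)
  expect_equal(rotated$radius, base$radius, tolerance = 1e-9)
})

test_that("20% gross outliers barely move the fitted radius", {
  for (s in 1:5) {
    good <- sphere_points(4000, c(0, 0, 0), 27.1, seed = 70 + s,
                          noise_sd = 0.03)
    out <- withr::with_seed(80 + s,
                            matrix(runif(3000, -35, 35), 1000))
    fit <- fit_sphere(rbind(good, out),
                      fit_config(n_samples = 40000, rng_seed = s))
    expect_lt(abs(fit$radius - 27.1), 0.1)
  }
})
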