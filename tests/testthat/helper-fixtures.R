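# Shared fixtures: a down-scaled phantom for unit tests (the full-size
# default is exercised in the acceptance suite), and synthetic sphere
# samples used as fitting oracles.

small_phantom_spec <- function(...) {
  defaults <- list(cup_outer_diameter = 20, cup_shell_thickness = 3,
                   dome_hole_diameter = 4, head_diameter = 9,
                   stem_radius = 2.5, grid_shape = c(128, 128, 112),
                   rng_seed = 5L)
  do.call(phantom_spec, utils::modifyList(defaults, list(...)))
}

# n points on (part of) a sphere, optionally with radial Gaussian noise.
sphere_points <- function(n, center = c(0, 0, 0), radius = 1, seed = 1L,
                          hemisphere = FALSE, noise_sd = 0) {
  withr::with_seed(seed, {
    z <- if (hemisphere) runif(n) else runif(n, -1, 1)
    phi <- runif(n, 0, 2 * pi)
    rho <- sqrt(pmax(1 - z^2, 0))
    u <- cbind(rho * cos(phi), rho * sin(phi), z)
    r <- radius + rnorm(n, 0, noise_sd)
    sweep(u * r, 2, center, "+")
  })
}

random_rotation <- function(seed) {
  withr::with_seed(seed, {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  })
}
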