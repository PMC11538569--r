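# Independent numerical oracles used across the suite.  These never
# call the package's own propagation or transmission code paths.

water <- medium("water", 1000, 1500)
resin <- medium("lens", 1180, 2700, 1160)
skull_bone <- medium("skull", 1912, 2300, 1626)

# Pressure transmission through a fluid slab between two half-spaces,
# obtained by solving the four interface boundary conditions (pressure
# and normal-velocity continuity at both faces) as a dense linear
# system.  Convention e^{+i omega t}, incident wave exp(-i k z);
# returns the transmitted amplitude at the slab exit face.
transfer_matrix_slab <- function(outer, slab, thickness, frequency) {
  w <- 2 * pi * frequency
  k1 <- w / outer$c_long; k2 <- w / slab$c_long
  r1 <- outer$density; r2 <- slab$density
  d <- thickness
  # unknowns: r (reflection), A, B (slab waves), t (transmission at z=d)
  # medium 1: e^{-i k1 z} + r e^{+i k1 z}
  # slab:     A e^{-i k2 z} + B e^{+i k2 z}
  # medium 3: t e^{-i k1 (z - d)}
  # velocity: v = (i/(w rho)) dp/dz
  M <- matrix(0+0i, 4, 4)
  b <- complex(4)
  # p continuity at z = 0:  1 + r = A + B
  M[1, ] <- c(1, -1, -1, 0); b[1] <- -1
  # v continuity at z = 0: (k1/r1)(1 - r) = (k2/r2)(A - B)
  M[2, ] <- c(k1 / r1, k2 / r2, -k2 / r2, 0); b[2] <- k1 / r1
  # p continuity at z = d
  e2m <- exp(-1i * k2 * d); e2p <- exp(1i * k2 * d)
  M[3, ] <- c(0, e2m, e2p, -1); b[3] <- 0
  # v continuity at z = d
  M[4, ] <- c(0, (k2 / r2) * e2m, -(k2 / r2) * e2p, -k1 / r1); b[4] <- 0
  sol <- solve(M, b)
  sol[4]
}

# On-axis pressure of a baffled circular piston by fine midpoint
# quadrature of the diffraction integral in polar coordinates
# (axisymmetric, so the angular integral is 2*pi analytically).
quad_piston_axis <- function(radius, z, u0, med, frequency, nr = 20000L) {
  w <- 2 * pi * frequency
  k <- w / med$c_long
  s <- (seq_len(nr) - 0.5) * radius / nr
  ds <- radius / nr
  r <- sqrt(z^2 + s^2)
  integral <- 2 * pi * sum(exp(-1i * k * r) / r * s) * ds
  (1i * w * med$density / (2 * pi)) * u0 * integral
}

# On-axis pressure behind a uniformly transmitting square aperture
# (side `a`, complex exit amplitude `amp` for a unit plane wave) by
# fine 2D midpoint quadrature of the diffraction integral.
quad_square_axis <- function(a, z, amp, med, frequency, n = 600L) {
  w <- 2 * pi * frequency
  k <- w / med$c_long
  xs <- (seq_len(n) - 0.5) * a / n - a / 2
  dS <- (a / n)^2
  u0 <- amp / (med$density * med$c_long)
  r <- sqrt(outer(xs^2, xs^2, `+`) + z^2)
  (1i * w * med$density / (2 * pi)) * u0 * sum(exp(-1i * k * r) / r) * dS
}

# Uniform source lattice covering a disc of radius `a` (for the
# discrete piston test), spacing `d`.  Interior cells carry the
# midpoint weight u0 * d^2; rim cells are weighted by their fractional
# coverage of the disc (8x8 subsampling) so the staircase edge does
# not dominate the quadrature error.
disc_lattice <- function(a, d, u0, ns = 8L) {
  xs <- seq(-a - d, a + d, by = d)
  g <- expand.grid(x = xs, y = xs)
  g <- g[g$x^2 + g$y^2 <= (a + d)^2, ]
  off <- ((seq_len(ns) - 0.5) / ns - 0.5) * d
  frac <- vapply(seq_len(nrow(g)), function(i) {
    mean(outer((g$x[i] + off)^2, (g$y[i] + off)^2, `+`) <= a^2)
  }, numeric(1))
  sel <- frac > 0
  list(pos = cbind(g$x[sel], g$y[sel], 0),
       strengths = u0 * d^2 * frac[sel] + 0i)
}

# synthetic field: sum of Gaussian lobes on a volume grid (known-peak
# input for the peak extractor and profile tools)
gaussian_field <- function(grid, centers, sigmas = 0.3e-3, amps = 1) {
  pts <- grid_points(grid)
  amps <- rep_len(amps, nrow(centers))
  sigmas <- rep_len(sigmas, nrow(centers))
  v <- numeric(nrow(pts))
  for (i in seq_len(nrow(centers))) {
    d2 <- rowSums(sweep(pts, 2, centers[i, ], `-`)^2)
    v <- v + amps[i] * exp(-d2 / (2 * sigmas[i]^2))
  }
  pressure_field(grid, v + 0i, 3e6)
}

# A reduced bilateral configuration for fast unit tests: 6 mm
# aperture (24 x 24 pixels), point-focus targets, coarse grid.
small_config <- function(targets = list(focus_target(c(0, 0, 3e-3))),
                         jitter = 0, seed = 7L, skull = TRUE) {
  media <- media_registry()
  structure(list(
    frequency = 3e6,
    media = media,
    lens = lens_spec(aperture = c(6e-3, 6e-3),
                     lens_medium = media$lens, outer_medium = media$water),
    skull = if (skull) skull_layer(media$skull, 250e-6, 0.5e-3) else NULL,
    targets = targets,
    holography = list(seed = as.integer(seed), jitter_radius = jitter,
                      mirror_x = FALSE, plane_spacing = 0.125e-3),
    grid = volume_grid(c(-1.5e-3, 1.5e-3), c(-0.5e-3, 0.5e-3),
                       c(2e-3, 4e-3), 0.125e-3),
    pulse = pulse_scheme()
  ), class = "holo_config")
}
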