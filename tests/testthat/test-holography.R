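k0_3mhz <- 2 * pi * 3e6 / 1500

test_that("virtual-source clouds honour counts, weights and the carrier", {
  tg <- list(focus_target(c(1.5e-3, 0, 3.5e-3), amplitude = 1),
             focus_target(c(-1.5e-3, 0, 3.5e-3), amplitude = 2))
  vs <- make_virtual_sources(tg, 0.25e-3, seed = 1, carrier_k = k0_3mhz)
  expect_equal(nrow(vs$positions), 200L)
  # per-focus strength sums carry the focus amplitudes
  s1 <- sum(vs$strengths[1:100]); s2 <- sum(vs$strengths[101:200])
  expect_equal(Mod(s1), 1, tolerance = 1e-12)
  expect_equal(Mod(s2), 2, tolerance = 1e-12)
  expect_equal(Arg(s1), wrap_phase(k0_3mhz * 3.5e-3), tolerance = 1e-9)
  # all sources inside the jitter ball
  d <- sqrt(rowSums(sweep(vs$positions[1:100, ], 2,
                          tg[[1]]$center, `-`)^2))
  expect_true(all(d <= 0.25e-3 + 1e-15))
})

test_that("zero jitter collapses to the target centres, seeds reproduce", {
  tg <- list(focus_target(c(1e-3, -2e-3, 3e-3), n_sources = 5L))
  vs0 <- make_virtual_sources(tg, 0, seed = 9, carrier_k = k0_3mhz)
  expect_true(all(vs0$positions == rep(tg[[1]]$center, each = 5L)))

  tg2 <- list(focus_target(c(0, 0, 3e-3)), focus_target(c(1e-3, 0, 4e-3)))
  a <- make_virtual_sources(tg2, 0.3e-3, seed = 42, carrier_k = k0_3mhz)
  b <- make_virtual_sources(tg2, 0.3e-3, seed = 42, carrier_k = k0_3mhz)
  expect_identical(a$positions, b$positions)
  expect_identical(a$strengths, b$strengths)
  c2 <- make_virtual_sources(tg2, 0.3e-3, seed = 43, carrier_k = k0_3mhz)
  expect_false(identical(a$positions, c2$positions))

  expect_error(make_virtual_sources(tg2, -1e-3, 1, carrier_k = k0_3mhz),
               "jitter_radius")
  expect_error(make_virtual_sources(list(), 0, 1, carrier_k = k0_3mhz),
               "nonempty")
})

test_that("mirror_x reuses the jitter cloud across a bilateral pair", {
  tg <- list(focus_target(c(1.5e-3, 0, 3.5e-3)),
             focus_target(c(-1.5e-3, 0, 3.5e-3)))
  vs <- make_virtual_sources(tg, 0.25e-3, seed = 4, carrier_k = k0_3mhz,
                             mirror_x = TRUE)
  l <- vs$positions[1:100, ]; r <- vs$positions[101:200, ]
  expect_equal(r[, 1], -l[, 1])
  expect_equal(r[, 2:3], l[, 2:3])
})

test_that("slab transmission matches an independent boundary-value oracle", {
  layer <- skull_layer(skull_bone, 250e-6, 0.5e-3)
  t_pkg <- skull_transmission(layer, 3e6, water)
  t_ora <- transfer_matrix_slab(water, skull_bone, 250e-6, 3e6)
  expect_equal(t_pkg, t_ora, tolerance = 1e-10)

  # vanishing layer passes unchanged
  thin <- skull_layer(skull_bone, 1e-12, 0)
  expect_equal(skull_transmission(thin, 3e6, water), 1 + 0i,
               tolerance = 1e-6)

  # impedance-matched slab is a pure delay of magnitude one
  d <- 250e-6
  matched <- skull_layer(water, d, 0)
  expect_equal(skull_transmission(matched, 3e6, water),
               exp(complex(imaginary = -2 * pi * 3e6 / 1500 * d)),
               tolerance = 1e-12)
})

test_that("|slab factor| <= 1 for physical media, = 1 iff matched", {
  set.seed(21)
  for (i in 1:25) {
    m <- medium("rand", runif(1, 500, 4000), runif(1, 800, 6000))
    d <- runif(1, 10e-6, 2e-3)
    tt <- skull_transmission(skull_layer(m, d, 0), 3e6, water)
    expect_lte(Mod(tt), 1 + 1e-12)
    # cross-check each draw against the boundary-value oracle
    expect_equal(tt, transfer_matrix_slab(water, m, d, 3e6),
                 tolerance = 1e-9)
  }
  mismatched <- skull_transmission(skull_layer(skull_bone, 200e-6, 0),
                                   3e6, water)
  expect_lt(Mod(mismatched), 1)
})

test_that("recorded phase matches the analytic spherical wave", {
  f <- 3e6
  focus <- c(0, 0, 3e-3)
  vs <- make_virtual_sources(list(focus_target(focus)), 0, seed = 1,
                             carrier_k = k0_3mhz)
  plane <- planar_grid(shape = c(16, 16), spacing = 0.25e-3)
  h <- record_hologram(vs, NULL, plane, water, f)
  pts <- grid_points(plane)
  r <- sqrt(rowSums(sweep(pts, 2, focus, `-`)^2))
  # relative phase across the plane is -k0 * (r - r_ref); the carrier
  # and i-prefactor are common offsets
  dphi <- wrap_phase(h$phase$values - h$phase$values[1])
  expect_equal(dphi, wrap_phase(-k0_3mhz * (r - r[1])), tolerance = 1e-9)
})

test_that("bilateral recordings are mirror-symmetric in magnitude", {
  tg <- list(focus_target(c(1.5e-3, 0, 3.5e-3)),
             focus_target(c(-1.5e-3, 0, 3.5e-3)))
  vs <- make_virtual_sources(tg, 0.25e-3, seed = 2, carrier_k = k0_3mhz,
                             mirror_x = TRUE)
  plane <- planar_grid(shape = c(24, 24), spacing = 0.25e-3)
  h <- record_hologram(vs, NULL, plane, water, 3e6)
  m <- matrix(Mod(h$pressure$values), 24, 24)
  expect_equal(m, m[24:1, ], tolerance = 1e-10)
})

test_that("the flat slab adds one uniform phase to the recording", {
  vs <- make_virtual_sources(list(focus_target(c(0.7e-3, 0, 3e-3))), 0,
                             seed = 1, carrier_k = k0_3mhz)
  plane <- planar_grid(shape = c(12, 12), spacing = 0.25e-3)
  layer <- skull_layer(skull_bone, 250e-6, 0.5e-3)
  h_on <- record_hologram(vs, layer, plane, water, 3e6)
  h_off <- record_hologram(vs, NULL, plane, water, 3e6)
  dphi <- wrap_phase(h_on$phase$values - h_off$phase$values)
  expect_equal(diff(range(dphi)), 0, tolerance = 1e-10)
  expect_equal(dphi[1], Arg(skull_transmission(layer, 3e6, water)),
               tolerance = 1e-10)
})

test_that("a recording plane inside the slab is refused", {
  vs <- make_virtual_sources(list(focus_target(c(0, 0, 3e-3))), 0,
                             seed = 1, carrier_k = k0_3mhz)
  plane_in <- planar_grid(center = c(0, 0, 0.6e-3), shape = c(8, 8),
                          spacing = 0.25e-3)
  layer <- skull_layer(skull_bone, 250e-6, 0.5e-3)
  expect_error(record_hologram(vs, layer, plane_in, water, 3e6),
               "intersects")
})

test_that("conjugation negates phases, preserves magnitudes, involutes", {
  plane <- planar_grid(shape = c(2, 2), spacing = 1e-3)
  vals <- c(exp(1i * pi / 3), exp(1i * pi) * 2, 0.5 + 0i, 1 - 1i)
  h <- structure(list(plane = plane,
                      pressure = pressure_field(plane, vals, 3e6),
                      phase = phase_of(pressure_field(plane, vals, 3e6)),
                      conjugated = FALSE, layer = NULL),
                 class = "hologram")
  hc <- conjugate(h)
  expect_true(hc$conjugated)
  expect_equal(hc$phase$values[1], -pi / 3)
  # -pi wraps to pi, whose negation rewraps to pi: a wrap fixed point
  expect_equal(hc$phase$values[2], pi)
  expect_equal(Mod(hc$pressure$values), Mod(vals))
  expect_error(conjugate(hc), "already conjugated")
  hcc <- conjugate(hc, force = TRUE)
  expect_false(hcc$conjugated)
  expect_equal(hcc$phase$values, h$phase$values)
})
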