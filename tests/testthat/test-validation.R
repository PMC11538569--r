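test_that("a flat lens radiates like a square piston on axis", {
  spec6 <- lens_spec(aperture = c(6e-3, 6e-3))
  h0 <- 0.4e-3
  np <- spec6$n_pixels
  map <- structure(list(spec = spec6, frequency = 3e6,
                        heights = matrix(h0, np[1], np[2]),
                        target_phase = matrix(0, np[1], np[2]),
                        residuals = matrix(0, np[1], np[2]),
                        amplitude = matrix(1, np[1], np[2]),
                        scan_step = 5e-6, quantized = TRUE),
                   class = "height_map")
  zs <- c(6e-3, 8e-3, 15e-3)
  grid <- volume_grid(c(0, 0), c(0, 0), range(zs), min(diff(zs)))
  fld <- simulate_field(map, NULL, grid, 3e6)
  amp <- slab_T(h0, spec6, 3e6)
  for (z in zs) {
    iz <- which.min(abs(grid$z - z))
    oracle <- quad_square_axis(6e-3, grid$z[iz], amp, water, 3e6)
    expect_lt(Mod(fld$values[iz] - oracle) / Mod(oracle), 0.01)
  }
  # extreme near field needs denser Huygens sampling: the lambda/4
  # default is ~1.5% at z = 4 mm, 4 sources/edge brings it under 1%
  gz4 <- volume_grid(c(0, 0), c(0, 0), c(4e-3, 4e-3), 1e-3)
  o4 <- quad_square_axis(6e-3, 4e-3, amp, water, 3e6)
  f4 <- simulate_field(map, NULL, gz4, 3e6, subsample = 4L)
  expect_lt(Mod(f4$values[1] - o4) / Mod(o4), 0.01)
  expect_error(simulate_field(map, NULL,
                              volume_grid(c(0, 0), c(0, 0),
                                          c(-1e-3, 1e-3), 0.5e-3), 3e6),
               "overlaps")
})

test_that("find_foci recovers constructed peaks and flags shortfalls", {
  grid <- volume_grid(c(-2.5e-3, 2.5e-3), c(-0.5e-3, 0.5e-3),
                      c(2.5e-3, 4.5e-3), 0.125e-3)
  two <- gaussian_field(grid, rbind(c(1.5e-3, 0, 3.5e-3),
                                    c(-1.5e-3, 0, 3.5e-3)))
  rep2 <- find_foci(two, 2)
  expect_equal(nrow(rep2$peaks), 2L)
  for (i in 1:2) {
    expect_lt(abs(abs(rep2$peaks$x[i]) - 1.5e-3), 0.125e-3)
    expect_lt(abs(rep2$peaks$z[i]) - 3.5e-3, 0.125e-3)
    expect_lt(abs(rep2$peaks$y[i]), 0.125e-3)
  }
  expect_equal(max(rep2$peaks$amplitude), 1)
  expect_lt(rep2$symmetry_error, 1e-6)
  # Gaussian FWHM = 2*sqrt(2*ln 2)*sigma
  expect_equal(rep2$peaks$fwhm_lateral[1], 2 * sqrt(2 * log(2)) * 0.3e-3,
               tolerance = 0.05)

  one <- gaussian_field(grid, rbind(c(0, 0, 3.5e-3)))
  expect_error(find_foci(one, 2), "insufficient peaks")
  expect_error(find_foci(one, 0), ">= 1")
})

test_that("line profiles interpolate, normalise and stay in bounds", {
  grid <- volume_grid(c(-2e-3, 2e-3), c(-0.5e-3, 0.5e-3),
                      c(2.5e-3, 4.5e-3), 0.125e-3)
  fld <- gaussian_field(grid, rbind(c(1e-3, 0, 3.5e-3)))
  ax <- line_profile(fld, "z", at = c(x = 1e-3, y = 0))
  expect_lt(abs(ax$profile$coordinate[which.max(ax$profile$amplitude)] -
                  3.5e-3), 0.07e-3)
  expect_equal(max(ax$profile$amplitude), 1, tolerance = 1e-6)
  lat <- line_profile(fld, "x", at = c(y = 0, z = 3.5e-3))
  expect_true(all(lat$profile$amplitude >= 0 &
                    lat$profile$amplitude <= 1 + 1e-12))
  expect_error(line_profile(fld, "z", at = c(x = 5e-3, y = 0)),
               "outside")
  expect_error(line_profile(fld, "z", at = c(x = 1e-3)), "must fix")
})

test_that("field correlation is scale-free and vanishes under shuffling", {
  grid <- volume_grid(c(-2e-3, 2e-3), c(-2e-3, 2e-3),
                      c(2e-3, 4e-3), 0.2e-3)   # 21*21*11 ~ 4851
  set.seed(31)
  fld <- gaussian_field(grid, rbind(c(0.5e-3, -0.5e-3, 3e-3)))
  expect_equal(field_correlation(fld, fld), 1)
  fld2 <- fld; fld2$values <- 2 * fld2$values
  expect_equal(field_correlation(fld, fld2), 1)
  shuf <- fld
  shuf$values <- fld$values[sample(length(fld$values))]
  expect_lt(abs(field_correlation(fld, shuf)), 0.1)
  other <- gaussian_field(volume_grid(c(-2e-3, 2e-3), c(-2e-3, 2e-3),
                                      c(2e-3, 4e-3), 0.25e-3),
                          rbind(c(0, 0, 3e-3)))
  expect_error(field_correlation(fld, other), "congruent")
})

test_that("phase-conjugate emission refocuses at the virtual sources", {
  # the core time-reversal property, checked for random target sets at
  # the design geometry (10 mm aperture, foci near 3.5 mm depth,
  # separated by the bilateral target spacing so the diffraction-
  # limited lobes are resolvable)
  k0 <- 2 * pi * 3e6 / 1500
  plane <- planar_grid(shape = c(80, 80), spacing = 0.125e-3)
  grid <- volume_grid(c(-2.2e-3, 2.2e-3), c(-0.6e-3, 0.6e-3),
                      c(2.8e-3, 4e-3), 0.125e-3)
  for (seed in c(303, 304)) {
    set.seed(seed)
    n_targets <- sample(1:3, 1)
    xs <- (seq_len(n_targets) - (n_targets + 1) / 2) * 1.5e-3 +
      runif(n_targets, -0.1e-3, 0.1e-3)
    centers <- cbind(xs, runif(n_targets, -0.3e-3, 0.3e-3),
                     runif(n_targets, 3.2e-3, 3.6e-3))
    targets <- lapply(seq_len(n_targets), function(i)
      focus_target(centers[i, ]))
    vs <- make_virtual_sources(targets, 0, seed = seed, carrier_k = k0)
    hol <- conjugate(record_hologram(vs, NULL, plane, water, 3e6))
    fld <- refocus_field(hol, grid, water, 3e6)
    rep <- find_foci(fld, n_targets)
    # each target matched by a peak within one grid cell
    for (i in seq_len(n_targets)) {
      d <- apply(rep$peaks[, c("x", "y", "z")], 1, function(p)
        max(abs(p - centers[i, ])))
      expect_lt(min(d), 0.125e-3 + 1e-12)
    }
  }
  raw <- record_hologram(
    make_virtual_sources(list(focus_target(c(0, 0, 3e-3))), 0, 1,
                         carrier_k = k0), NULL, plane, water, 3e6)
  expect_error(refocus_field(raw, volume_grid(c(0, 0), c(0, 0),
                                              c(1e-3, 2e-3), 0.5e-3),
                             water, 3e6),
               "conjugated")
})

test_that("peak positions are grid-converged", {
  k0 <- 2 * pi * 3e6 / 1500
  vs <- make_virtual_sources(list(focus_target(c(0.3e-3, 0, 3e-3))), 0,
                             seed = 5, carrier_k = k0)
  plane <- planar_grid(shape = c(48, 48), spacing = 0.125e-3)
  hol <- conjugate(record_hologram(vs, NULL, plane, water, 3e6))
  peak_at <- function(sp) {
    g <- volume_grid(c(-0.5e-3, 1.1e-3), c(-0.4e-3, 0.4e-3),
                     c(2.4e-3, 3.6e-3), sp)
    r <- find_foci(refocus_field(hol, g, water, 3e6), 1)
    unlist(r$peaks[1, c("x", "y", "z")])
  }
  p_coarse <- peak_at(0.2e-3)
  p_fine <- peak_at(0.1e-3)
  expect_lt(max(abs(p_coarse - p_fine)), 0.05e-3)
})

test_that("thickness sweep is deterministic and handles edge lists", {
  spec2 <- lens_spec(aperture = c(2e-3, 2e-3))
  np <- spec2$n_pixels
  map <- structure(list(spec = spec2, frequency = 3e6,
                        heights = matrix(0.2e-3, np[1], np[2]),
                        target_phase = matrix(0, np[1], np[2]),
                        residuals = matrix(0, np[1], np[2]),
                        amplitude = matrix(1, np[1], np[2]),
                        scan_step = 5e-6, quantized = TRUE),
                   class = "height_map")
  layer <- skull_layer(skull_bone, 250e-6, 0.5e-3)
  grid <- volume_grid(c(-0.5e-3, 0.5e-3), c(0, 0), c(2e-3, 3e-3), 0.25e-3)
  empty <- thickness_sweep(map, layer, numeric(0), grid, 3e6, n = 1)
  expect_length(empty, 0L)
  dup <- thickness_sweep(map, layer, c(200e-6, 200e-6), grid, 3e6, n = 1)
  expect_equal(dup[[1]], dup[[2]])
})
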