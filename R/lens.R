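#' Holographic lens geometry and materials
#'
#' Geometry of the printable phase plate: a square-pixel relief of
#' uniform lateral pitch `pixel_width` on a base slab of thickness
#' `base_thickness`, printed in `lens_medium` and immersed in
#' `outer_medium`.  Pixel heights range over `[0, h_max]`; the default
#' `h_max = 1.2` mm covers a full 2*pi of relative phase at 3 MHz (the
#' thin-slab phase rate for the resin/water pair is ~0.89 cycles/mm, so
#' ~1.13 mm spans a cycle) while keeping `base + h_max` within the 2 mm
#' build height.
#'
#' @param aperture numeric length-2 lateral extent (width, height), m.
#' @param pixel_width square pixel pitch, m (design value 0.25 mm).
#' @param base_thickness base slab thickness `l` at h = 0, m.
#' @param h_max maximum pixel height, m.
#' @param lens_medium,outer_medium [medium()] objects.
#' @param print_resolution printer voxel pitch, m (100 um).
#' @param build_height maximum total thickness, m.
#' @return object of class `"lens_spec"` (adds `n_pixels`, the pixel
#'   counts along each aperture axis).
#' @examples
#' lens_spec()$n_pixels  # 40 x 40
#' @export
lens_spec <- function(aperture = c(10e-3, 10e-3), pixel_width = 0.25e-3,
                      base_thickness = 0.8e-3, h_max = 1.2e-3,
                      lens_medium = media_registry()$lens,
                      outer_medium = media_registry()$water,
                      print_resolution = 100e-6, build_height = 2e-3) {
  check_positive(pixel_width, "pixel_width")
  check_positive(base_thickness, "base_thickness")
  check_positive(h_max, "h_max")
  check_positive(print_resolution, "print_resolution")
  stopifnot(length(aperture) == 2L, all(aperture > 0),
            inherits(lens_medium, "medium"), inherits(outer_medium, "medium"))
  np <- aperture / pixel_width
  if (any(abs(np - round(np)) > 1e-9)) {
    stop("`aperture` must divide into whole pixels of `pixel_width`",
         call. = FALSE)
  }
  if (base_thickness + h_max > build_height + 1e-12) {
    stop("`base_thickness + h_max` exceeds the build height", call. = FALSE)
  }
  structure(list(aperture = as.numeric(aperture), pixel_width = pixel_width,
                 base_thickness = base_thickness, h_max = h_max,
                 lens_medium = lens_medium, outer_medium = outer_medium,
                 print_resolution = print_resolution,
                 build_height = build_height,
                 n_pixels = as.integer(round(np))),
            class = "lens_spec")
}

#' Complex transmission of one lens pixel
#'
#' Transmission coefficient of a resin slab of thickness `h` standing
#' on the lens base, evaluated at the holographic-lens exit surface
#' z = l (the remaining `l - h` of the path is water):
#' \deqn{T(h) = \frac{2Z\,e^{-ik_0[l-h]}}
#'       {2Z\cos(k_L h) + i(Z^2+1)\sin(k_L h)}}
#' with \eqn{Z = Z_L/Z_0} the normalised resin impedance, \eqn{k_0} and
#' \eqn{k_L} the water and resin wavenumbers.  `|T| <= 1` always (the
#' denominator magnitude is bounded below by the numerator's since
#' \eqn{(Z^2+1)^2 \ge 4Z^2}), with equality at h = 0 and at resin
#' half-wave resonances \eqn{k_L h = m\pi}.
#'
#' @param h pixel height(s), m, in `[0, h_max]`; vectorised.
#' @param spec a [lens_spec()].
#' @param frequency Hz.
#' @return complex transmission, same length as `h`.
#' @export
slab_T <- function(h, spec, frequency) {
  stopifnot(inherits(spec, "lens_spec"))
  check_positive(frequency, "frequency")
  if (any(h < -1e-15 | h > spec$h_max + 1e-15)) {
    stop("`h` must lie in [0, h_max]", call. = FALSE)
  }
  Z <- acoustic_impedance(spec$lens_medium) /
    acoustic_impedance(spec$outer_medium)
  k0 <- wavenumber(spec$outer_medium, frequency)
  kL <- wavenumber(spec$lens_medium, frequency)
  l <- spec$base_thickness
  2 * Z * exp(complex(imaginary = -k0 * (l - h))) /
    (2 * Z * cos(kL * h) + 1i * (Z^2 + 1) * sin(kL * h))
}

#' Phase imposed by one lens pixel
#'
#' Wrapped argument of [slab_T()]: the phase of the transmitted wave at
#' the lens exit surface as a function of pixel height.
#'
#' @inheritParams slab_T
#' @return phase, radians in `(-pi, pi]`, same length as `h`.
#' @export
slab_phase <- function(h, spec, frequency) {
  Arg(slab_T(h, spec, frequency))
}

#' Invert a target phase into a pixel height
#'
#' Exhaustive scan of `h` over `[0, h_max]` in steps of `scan_step`,
#' returning the height whose [slab_phase()] is closest (in wrapped
#' distance) to the target; ties break to the smallest height.  A scan
#' is used instead of root finding because the pixel phase is
#' non-monotone across the slab resonances.
#'
#' @param target_phase radians in `(-pi, pi]`; vectorised.
#' @param spec a [lens_spec()].
#' @param frequency Hz.
#' @param scan_step scan resolution, m.
#' @return list with `h` (m) and `residual` (radians, absolute wrapped
#'   mismatch), each the length of `target_phase`.
#' @examples
#' sp <- lens_spec()
#' solve_height(slab_phase(0.6e-3, sp, 3e6), sp, 3e6)$h
#' @export
solve_height <- function(target_phase, spec, frequency, scan_step = 5e-6) {
  stopifnot(inherits(spec, "lens_spec"))
  check_positive(scan_step, "scan_step")
  if (spec$h_max < scan_step) {
    stop("empty height scan: `h_max` is smaller than `scan_step`",
         call. = FALSE)
  }
  if (any(target_phase <= -pi - 1e-12 | target_phase > pi + 1e-12)) {
    stop("`target_phase` must lie in (-pi, pi]", call. = FALSE)
  }
  hs <- seq(0, spec$h_max, by = scan_step)
  if (hs[length(hs)] < spec$h_max) hs <- c(hs, spec$h_max)
  ph <- slab_phase(hs, spec, frequency)
  # residual matrix: scan heights x targets; which.min takes the first
  # (= smallest h) minimiser.
  res <- abs(wrap_phase(outer(ph, target_phase, `-`)))
  best <- apply(res, 2L, which.min)
  list(h = hs[best], residual = res[cbind(best, seq_along(best))])
}

#' Design the lens height map from a conjugated hologram
#'
#' Resamples the conjugated hologram onto the pixel lattice (mean of
#' the complex field over each pixel footprint, then argument — robust
#' to sub-pixel phase gradients), and inverts each pixel's target phase
#' into a height with [solve_height()].  The plane sampling must tile
#' the pixels exactly (an integer number of plane samples per pixel
#' covering the aperture).
#'
#' @param hologram a conjugated [record_hologram()] result.
#' @param spec a [lens_spec()].
#' @param frequency Hz.
#' @param scan_step height-scan resolution for [solve_height()], m.
#' @return object of class `"height_map"`: `heights`, `target_phase`,
#'   `residuals`, `amplitude` (|T| per pixel) — all n_pixels matrices —
#'   plus `spec`, `frequency`, `quantized = FALSE`.
#' @export
design_height_map <- function(hologram, spec, frequency, scan_step = 5e-6) {
  stopifnot(inherits(hologram, "hologram"), inherits(spec, "lens_spec"))
  if (!hologram$conjugated) {
    stop("hologram must be conjugated before lens design", call. = FALSE)
  }
  plane <- hologram$plane
  npx <- spec$n_pixels
  sub <- plane$shape / npx
  if (any(abs(sub - round(sub)) > 1e-9) ||
      abs(plane$spacing * plane$shape[1] - spec$aperture[1]) > 1e-9 ||
      abs(plane$spacing * plane$shape[2] - spec$aperture[2]) > 1e-9) {
    stop("hologram plane is not congruent with the lens pixel lattice",
         call. = FALSE)
  }
  sub <- as.integer(round(sub))
  vals <- matrix(hologram$pressure$values, plane$shape[1], plane$shape[2])
  # block mean over each pixel footprint
  gx <- rep(seq_len(npx[1]), each = sub[1])
  gy <- rep(seq_len(npx[2]), each = sub[2])
  block_sum <- function(m) t(rowsum(t(rowsum(m, gx, reorder = FALSE)),
                                    gy, reorder = FALSE))
  means <- complex(real = block_sum(Re(vals)),
                   imaginary = block_sum(Im(vals))) / (sub[1] * sub[2])
  means <- matrix(means, npx[1], npx[2])
  target <- Arg(means)
  target[Mod(means) == 0] <- 0

  sol <- solve_height(as.vector(target), spec, frequency, scan_step)
  heights <- matrix(sol$h, npx[1], npx[2])
  structure(list(spec = spec, frequency = frequency,
                 heights = heights,
                 target_phase = target,
                 residuals = matrix(sol$residual, npx[1], npx[2]),
                 amplitude = matrix(Mod(slab_T(sol$h, spec, frequency)),
                                    npx[1], npx[2]),
                 scan_step = scan_step, quantized = FALSE),
            class = "height_map")
}

#' Quantize a height map to the printer resolution
#'
#' Rounds every pixel height to the nearest multiple of the print
#' resolution, clamps to `[0, h_max]`, and recomputes the phase
#' residuals and per-pixel |T| for the quantized heights.  Quantizing
#' an already-quantized map is an identity.
#'
#' @param map a [design_height_map()] result.
#' @return the quantized `"height_map"` (`quantized = TRUE`).
#' @export
quantize_heights <- function(map) {
  stopifnot(inherits(map, "height_map"))
  res <- map$spec$print_resolution
  hmax_q <- res * floor(map$spec$h_max / res + 1e-9)
  h <- pmin(pmax(round(map$heights / res) * res, 0), hmax_q)
  ph <- slab_phase(as.vector(h), map$spec, map$frequency)
  map$heights <- h
  map$residuals <- matrix(abs(wrap_phase(ph - as.vector(map$target_phase))),
                          nrow(h), ncol(h))
  map$amplitude <- matrix(Mod(slab_T(as.vector(h), map$spec, map$frequency)),
                          nrow(h), ncol(h))
  map$quantized <- TRUE
  map
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf(
    "<height_map> %d x %d pixels (%.2f mm pitch), h in [%.3g, %.3g] mm, %s\n",
    nrow(x$heights), ncol(x$heights), x$spec$pixel_width * 1e3,
    min(x$heights) * 1e3, max(x$heights) * 1e3,
    if (x$quantized) sprintf("quantized to %g um", x$spec$print_resolution * 1e6)
    else "unquantized"))
  cat(sprintf("  phase residual: max %.4f rad, mean %.4f rad\n",
              max(x$residuals), mean(x$residuals)))
  invisible(x)
}
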