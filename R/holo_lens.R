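#' Design a multifocal holographic lens
#'
#' The package's central fitting function.  Given a run configuration
#' it (1) places seeded virtual sources at the focal targets,
#' (2) records their field on the holographic plane through the skull
#' slab by time reversal, (3) phase-conjugates the recording, and
#' (4) inverts the conjugated phase pixel-by-pixel into printable resin
#' heights through the slab transmission coefficient, quantized to the
#' printer resolution.  The estimator is the per-pixel height that
#' minimises the wrapped mismatch between the pixel's transmission
#' phase and the conjugated hologram phase; the residual of that fit is
#' available via [residuals.holo_lens()], and [predict.holo_lens()]
#' forward-simulates the transmitted field.
#'
#' @param config a `"holo_config"` (default [bilateral_ds_fixture()]).
#' @param scan_step height-scan resolution for the inverse step, m.
#' @param quantize quantize heights to the printer resolution.
#' @param record_through_skull include the skull slab in the recording
#'   step (its transmission phase is then compensated by the lens).
#' @return object of class `"holo_lens"` with components `config`,
#'   `sources`, `hologram` (conjugated), `map_raw` (unquantized
#'   height map), `map` (as printed), and `call`.
#' @examples
#' \donttest{
#' lens <- design_lens(bilateral_ds_fixture())
#' lens
#' rep <- find_foci(predict(lens), n = 2)
#' rep
#' }
#' @seealso [find_foci()], [thickness_sweep()], [write_stl()]
#' @export
design_lens <- function(config = bilateral_ds_fixture(), scan_step = 5e-6,
                        quantize = TRUE, record_through_skull = TRUE) {
  validate_config(config)
  f <- config$frequency
  water <- config$media$water
  k0 <- wavenumber(water, f)
  holo <- config$holography
  sources <- make_virtual_sources(config$targets,
                                  jitter_radius = holo$jitter_radius,
                                  seed = holo$seed, carrier_k = k0,
                                  mirror_x = holo$mirror_x)
  plane <- planar_grid(center = c(0, 0, 0),
                       shape = round(config$lens$aperture / holo$plane_spacing),
                       spacing = holo$plane_spacing)
  layer <- if (record_through_skull) config$skull else NULL
  hol <- conjugate(record_hologram(sources, layer, plane, water, f))
  map_raw <- design_height_map(hol, config$lens, f, scan_step)
  map <- if (quantize) quantize_heights(map_raw) else map_raw
  structure(list(config = config, sources = sources, hologram = hol,
                 map_raw = map_raw, map = map, frequency = f,
                 call = match.call()),
            class = "holo_lens")
}

#' @export
print.holo_lens <- function(x, ...) {
  cfg <- x$config
  cat("Holographic lens design\n")
  cat(sprintf("  frequency: %g MHz, aperture %g x %g mm, %d x %d pixels\n",
              x$frequency / 1e6, cfg$lens$aperture[1] * 1e3,
              cfg$lens$aperture[2] * 1e3,
              cfg$lens$n_pixels[1], cfg$lens$n_pixels[2]))
  cat(sprintf("  targets: %s\n", paste(vapply(cfg$targets, function(t)
    sprintf("(%g, %g, %g) mm", t$center[1] * 1e3, t$center[2] * 1e3,
            t$center[3] * 1e3), character(1)), collapse = ", ")))
  cat(sprintf("  skull in recording: %s\n",
              if (is.null(x$hologram$layer)) "no"
              else sprintf("%g um slab", x$hologram$layer$thickness * 1e6)))
  cat(sprintf("  heights: [%.3g, %.3g] mm%s; max phase residual %.3f rad\n",
              min(x$map$heights) * 1e3, max(x$map$heights) * 1e3,
              if (x$map$quantized) " (quantized)" else "",
              max(x$map$residuals)))
  invisible(x)
}

#' Summarise a lens design
#'
#' @param object a [design_lens()] result.
#' @param ... unused.
#' @return a `"summary.holo_lens"` with residual quantiles, |T| range
#'   and geometry bookkeeping.
#' @export
summary.holo_lens <- function(object, ...) {
  m <- object$map
  structure(list(
    lens = object,
    residual_quantiles = stats::quantile(m$residuals,
                                         c(0, 0.5, 0.9, 0.99, 1)),
    amplitude_range = range(m$amplitude),
    height_range = range(m$heights),
    n_pixels = prod(object$config$lens$n_pixels)
  ), class = "summary.holo_lens")
}

#' @export
print.summary.holo_lens <- function(x, ...) {
  print(x$lens)
  cat(sprintf("  %d pixels; |T| in [%.3f, %.3f]\n", x$n_pixels,
              x$amplitude_range[1], x$amplitude_range[2]))
  cat("  phase residual quantiles (rad):\n")
  print(round(x$residual_quantiles, 4))
  invisible(x)
}

#' Pixel heights of a designed lens
#'
#' @param object a [design_lens()] result.
#' @param ... unused.
#' @return the (quantized) height matrix, metres.
#' @export
coef.holo_lens <- function(object, ...) object$map$heights

#' Phase residuals of the height fit
#'
#' Absolute wrapped mismatch between each pixel's transmission phase
#' and the conjugated hologram phase it was fitted to.
#'
#' @param object a [design_lens()] result.
#' @param quantized residuals of the printed (quantized) map, else of
#'   the continuous fit.
#' @param ... unused.
#' @return matrix of residuals, radians.
#' @export
residuals.holo_lens <- function(object, quantized = TRUE, ...) {
  if (quantized) object$map$residuals else object$map_raw$residuals
}

#' Forward-simulate the field of a designed lens
#'
#' Runs [simulate_field()] for the design: a unit plane wave through
#' the printed height map and (by default) the configured skull slab,
#' evaluated on the configured grid.
#'
#' @param object a [design_lens()] result.
#' @param grid evaluation [volume_grid()]; default from the config.
#' @param skull include the skull slab.
#' @param thickness override slab thickness, m (e.g. for robustness
#'   checks); ignored when `skull = FALSE`.
#' @param ... unused.
#' @return a [pressure_field()].
#' @export
predict.holo_lens <- function(object, grid = NULL, skull = TRUE,
                              thickness = NULL, ...) {
  if (is.null(grid)) grid <- object$config$grid
  layer <- NULL
  if (skull && !is.null(object$config$skull)) {
    layer <- object$config$skull
    if (!is.null(thickness)) {
      layer <- skull_layer(layer$medium, thickness, layer$z_entry)
    }
  }
  simulate_field(object$map, layer, grid, object$frequency)
}

#' Plot a lens design
#'
#' Image of the pixel height relief (default) or of the phase
#' residuals, in millimetres over the lens aperture.
#'
#' @param x a [design_lens()] result.
#' @param what `"heights"` or `"residuals"`.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.holo_lens <- function(x, what = c("heights", "residuals"), ...) {
  what <- match.arg(what)
  spec <- x$config$lens
  np <- spec$n_pixels
  cx <- (seq_len(np[1]) - (np[1] + 1) / 2) * spec$pixel_width * 1e3
  cy <- (seq_len(np[2]) - (np[2] + 1) / 2) * spec$pixel_width * 1e3
  z <- if (what == "heights") x$map$heights * 1e3 else x$map$residuals
  graphics::image(cx, cy, z, asp = 1, xlab = "x (mm)", ylab = "y (mm)",
                  main = if (what == "heights") "pixel height (mm)"
                  else "phase residual (rad)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}
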