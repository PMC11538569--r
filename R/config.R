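#' Bilateral dorsal-striatum design configuration
#'
#' The complete built-in configuration of the bilateral
#' dorsal-striatum bifocal lens: 3 MHz working frequency, the built-in
#' water/resin/skull media, a 10 mm x 10 mm aperture of 0.25 mm pixels
#' (40 x 40), a 250 um flat skull slab at 0.5 mm standoff, and two foci
#' of 100 virtual sources each at (x, y, z) = (+/-1.5, 0, 3.5) mm.
#' The jitter clouds of the bilateral pair are mirrored in x so the
#' design is exactly symmetric for any seed.
#'
#' @param seed integer seed for the virtual-source draw.
#' @return object of class `"holo_config"`: named list with
#'   `frequency`, `media`, `lens`, `skull`, `targets`, `holography`
#'   (seed, jitter_radius, mirror_x, plane_spacing) and `grid`
#'   (evaluation region), all in SI units.
#' @examples
#' cfg <- bilateral_ds_fixture()
#' cfg$lens$n_pixels
#' @export
bilateral_ds_fixture <- function(seed = 1234L) {
  media <- media_registry()
  cfg <- structure(list(
    frequency = 3e6,
    media = media,
    lens = lens_spec(lens_medium = media$lens, outer_medium = media$water),
    skull = skull_layer(media$skull, thickness = 250e-6, z_entry = 0.5e-3),
    targets = list(
      focus_target(c( 1.5e-3, 0, 3.5e-3), amplitude = 1, n_sources = 100L),
      focus_target(c(-1.5e-3, 0, 3.5e-3), amplitude = 1, n_sources = 100L)
    ),
    holography = list(seed = as.integer(seed), jitter_radius = 0.25e-3,
                      mirror_x = TRUE, plane_spacing = 0.125e-3),
    grid = volume_grid(c(-2.5e-3, 2.5e-3), c(-0.5e-3, 0.5e-3),
                       c(2.5e-3, 5.5e-3), 0.125e-3),
    pulse = pulse_scheme()
  ), class = "holo_config")
  validate_config(cfg)
  cfg
}

#' Validate a run configuration
#'
#' Checks the cross-section invariants a config must satisfy before a
#' design run: media present, recording plane congruent with the pixel
#' lattice and outside the skull slab, the evaluation grid downstream
#' of the lens, and targets beyond the skull.
#'
#' @param cfg a `"holo_config"` list.
#' @return `cfg`, invisibly; errors name the offending section.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "holo_config"))
  for (nm in c("frequency", "media", "lens", "targets", "holography")) {
    if (is.null(cfg[[nm]])) {
      stop(sprintf("config is missing section '%s'", nm), call. = FALSE)
    }
  }
  check_positive(cfg$frequency, "frequency")
  stopifnot(inherits(cfg$lens, "lens_spec"))
  if (!is.null(cfg$skull)) {
    stopifnot(inherits(cfg$skull, "skull_layer"))
    z1 <- cfg$skull$z_entry + cfg$skull$thickness
    for (tg in cfg$targets) {
      if (tg$center[3] <= z1) {
        stop("config: a focal target lies inside or before the skull slab",
             call. = FALSE)
      }
    }
  }
  sub <- cfg$lens$pixel_width / cfg$holography$plane_spacing
  if (abs(sub - round(sub)) > 1e-9) {
    stop("config: plane_spacing must divide the lens pixel width",
         call. = FALSE)
  }
  if (!is.null(cfg$grid)) {
    stopifnot(inherits(cfg$grid, "volume_grid"))
    if (min(cfg$grid$z) <= 0) {
      stop("config: evaluation grid must lie downstream of the lens (z > 0)",
           call. = FALSE)
    }
  }
  invisible(cfg)
}

#' Read a run configuration from JSON
#'
#' Parses a JSON document whose keys carry explicit units (mm, MHz,
#' kg/m^3, m/s — the unit is part of each key name) and converts to SI
#' at parse time.  See `system.file("extdata", "bilateral_ds.json",
#' package = "holofocus")` for the schema; omitted sections fall back
#' to the built-in bilateral fixture values.
#'
#' @param path path to a JSON config file.
#' @return a validated `"holo_config"` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  med <- function(nm) {
    m <- j$media[[nm]]
    if (is.null(m)) return(media_registry()[[nm]])
    medium(nm, m$density_kg_m3, m$c_long_m_s,
           if (is.null(m$c_shear_m_s)) NA_real_ else m$c_shear_m_s)
  }
  media <- list(water = med("water"), lens = med("lens"), skull = med("skull"))
  frequency <- (if (is.null(j$frequency_mhz)) 3 else j$frequency_mhz) * 1e6
  lj <- if (is.null(j$lens)) list() else j$lens
  gv <- function(x, dflt) if (is.null(x)) dflt else x
  lens <- lens_spec(
    aperture = gv(lj$aperture_mm, c(10, 10)) * 1e-3,
    pixel_width = gv(lj$pixel_width_mm, 0.25) * 1e-3,
    base_thickness = gv(lj$base_thickness_mm, 0.8) * 1e-3,
    h_max = gv(lj$h_max_mm, 1.2) * 1e-3,
    lens_medium = media$lens, outer_medium = media$water,
    print_resolution = gv(lj$print_resolution_mm, 0.1) * 1e-3
  )
  sk <- NULL
  if (!isTRUE(j$skull$absent)) {
    sj <- if (is.null(j$skull)) list() else j$skull
    sk <- skull_layer(media$skull,
                      thickness = gv(sj$thickness_mm, 0.25) * 1e-3,
                      z_entry = gv(sj$standoff_mm, 0.5) * 1e-3)
  }
  targets <- if (is.null(j$targets)) {
    bilateral_ds_fixture()$targets
  } else {
    tj <- j$targets
    if (is.data.frame(tj)) {
      lapply(seq_len(nrow(tj)), function(i) {
        focus_target(unlist(tj$center_mm[i]) * 1e-3,
                     amplitude = gv(tj$amplitude[i], 1),
                     n_sources = gv(tj$n_sources[i], 100L))
      })
    } else {
      lapply(tj, function(t)
        focus_target(unlist(t$center_mm) * 1e-3,
                     amplitude = gv(t$amplitude, 1),
                     n_sources = gv(t$n_sources, 100L)))
    }
  }
  hj <- if (is.null(j$holography)) list() else j$holography
  gj <- if (is.null(j$grid)) list() else j$grid
  grid <- volume_grid(gv(gj$x_mm, c(-2.5, 2.5)) * 1e-3,
                      gv(gj$y_mm, c(-0.5, 0.5)) * 1e-3,
                      gv(gj$z_mm, c(2.5, 5.5)) * 1e-3,
                      gv(gj$spacing_mm, 0.125) * 1e-3)
  pj <- if (is.null(j$pulse)) list() else j$pulse
  pulse <- pulse_scheme(ff = gv(pj$ff_mhz, 3) * 1e6,
                        prf = gv(pj$prf_hz, 500),
                        tbd = gv(pj$tbd_ms, 0.4) * 1e-3,
                        sd = gv(pj$sd_s, 1), isi = gv(pj$isi_s, 4),
                        session = gv(pj$session_min, 20) * 60)
  cfg <- structure(list(
    frequency = frequency, media = media, lens = lens, skull = sk,
    targets = targets,
    holography = list(seed = as.integer(gv(hj$seed, 1234L)),
                      jitter_radius = gv(hj$jitter_radius_mm, 0.25) * 1e-3,
                      mirror_x = isTRUE(gv(hj$mirror_x, TRUE)),
                      plane_spacing = gv(hj$plane_spacing_mm, 0.125) * 1e-3),
    grid = grid, pulse = pulse
  ), class = "holo_config")
  validate_config(cfg)
  cfg
}

#' @export
print.holo_config <- function(x, ...) {
  cat(sprintf("<holo_config> %g MHz, %d target(s), %s skull, seed %d\n",
              x$frequency / 1e6, length(x$targets),
              if (is.null(x$skull)) "no"
              else sprintf("%g um", x$skull$thickness * 1e6),
              x$holography$seed))
  invisible(x)
}
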