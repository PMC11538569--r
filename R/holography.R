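#' Focal target for time-reversal recording
#'
#' One desired focus of the multifocal beam: its centre, a relative
#' amplitude weight, and the number of virtual point sources spread over
#' it during the recording step.
#'
#' @param center numeric length-3 (x, y, z), metres.
#' @param amplitude relative weight, positive.
#' @param n_sources virtual sources representing this focus (default
#'   100, the bilateral-striatum design value).
#' @return object of class `"focus_target"`.
#' @export
focus_target <- function(center, amplitude = 1, n_sources = 100L) {
  stopifnot(length(center) == 3L, is.finite(center))
  check_positive(amplitude, "amplitude")
  n_sources <- as.integer(n_sources)
  if (n_sources < 1L) stop("`n_sources` must be >= 1", call. = FALSE)
  structure(list(center = as.numeric(center), amplitude = amplitude,
                 n_sources = n_sources),
            class = "focus_target")
}

#' Virtual-source cloud for time-reversal recording
#'
#' Places `n_sources` seeded uniform draws inside a ball of
#' `jitter_radius` about each target centre (spreading the focal spot
#' over the nucleus-scale target volume; radius 0 collapses to a point
#' focus).  Each source carries strength
#' `amplitude / n_sources * exp(i * carrier_k * z_center)`: the carrier
#' factor removes the nominal plane-wave arrival phase of the
#' wavefront, referencing every focus to a common emission phase.
#'
#' With `mirror_x = TRUE`, a target whose centre is the x-mirror of an
#' earlier target reuses that target's jitter cloud with x negated, so
#' bilaterally symmetric designs stay exactly symmetric for any seed.
#'
#' @param targets list of [focus_target()]s.
#' @param jitter_radius ball radius, metres, >= 0.
#' @param seed integer seed; the draw is reproducible bit-for-bit.
#' @param carrier_k carrier wavenumber k_z, rad/m (the water wavenumber
#'   at the working frequency).
#' @param mirror_x mirror jitter clouds across x = 0 for bilateral
#'   target pairs.
#' @return object of class `"virtual_sources"`: `positions` (matrix),
#'   `strengths` (complex), `carrier_k`, `targets`, `seed`.
#' @examples
#' w <- media_registry()$water
#' k0 <- wavenumber(w, 3e6)
#' tg <- list(focus_target(c(1.5e-3, 0, 3.5e-3)),
#'            focus_target(c(-1.5e-3, 0, 3.5e-3)))
#' vs <- make_virtual_sources(tg, 0.25e-3, seed = 1, carrier_k = k0)
#' nrow(vs$positions)  # 200
#' @export
make_virtual_sources <- function(targets, jitter_radius = 0.25e-3,
                                 seed = 1L, carrier_k,
                                 mirror_x = FALSE) {
  if (length(targets) == 0L) stop("`targets` must be nonempty", call. = FALSE)
  stopifnot(all(vapply(targets, inherits, logical(1), "focus_target")))
  if (jitter_radius < 0) {
    stop("`jitter_radius` must be >= 0", call. = FALSE)
  }
  check_positive(carrier_k, "carrier_k")

  offsets <- with_seed(seed, {
    lapply(targets, function(tg) {
      n <- tg$n_sources
      if (jitter_radius == 0) return(matrix(0, n, 3L))
      r <- jitter_radius * stats::runif(n)^(1 / 3)
      dir <- matrix(stats::rnorm(3L * n), n, 3L)
      nrm <- sqrt(rowSums(dir^2))
      nrm[nrm == 0] <- 1
      dir * (r / nrm)
    })
  })

  if (mirror_x) {
    centers <- t(vapply(targets, `[[`, numeric(3), "center"))
    for (i in seq_along(targets)) {
      mirr <- c(-centers[i, 1], centers[i, 2:3])
      j <- which(apply(centers[seq_len(i - 1L), , drop = FALSE], 1L,
                       function(cc) isTRUE(all.equal(cc, mirr,
                                                     tolerance = 1e-12))))
      if (length(j)) {
        offsets[[i]] <- offsets[[j[1L]]] %*% diag(c(-1, 1, 1))
      }
    }
  }

  pos <- do.call(rbind, lapply(seq_along(targets), function(i) {
    sweep(offsets[[i]], 2L, targets[[i]]$center, `+`)
  }))
  strengths <- do.call(c, lapply(targets, function(tg) {
    rep(tg$amplitude / tg$n_sources *
          exp(complex(imaginary = carrier_k * tg$center[3])), tg$n_sources)
  }))
  dimnames(pos) <- list(NULL, c("x", "y", "z"))
  structure(list(positions = pos, strengths = strengths,
                 carrier_k = carrier_k, targets = targets,
                 seed = as.integer(seed)),
            class = "virtual_sources")
}

#' Flat skull layer
#'
#' The skull is modelled as a flat fluid slab at normal incidence using
#' its longitudinal sound speed; shear conversion in the thin
#' (~lambda/3) layer is neglected.  `z_entry` is the standoff of the
#' slab's near face from the holographic plane (z = 0).
#'
#' @param medium skull [medium()].
#' @param thickness slab thickness, metres (design default 250e-6).
#' @param z_entry standoff, metres, >= 0.
#' @return object of class `"skull_layer"`.
#' @export
skull_layer <- function(medium = media_registry()$skull,
                        thickness = 250e-6, z_entry = 0.5e-3) {
  stopifnot(inherits(medium, "medium"))
  check_positive(thickness, "thickness")
  check_nonnegative(z_entry, "z_entry")
  structure(list(medium = medium, thickness = thickness,
                 z_entry = z_entry, geometry = "flat-slab"),
            class = "skull_layer")
}

#' Normal-incidence transmission through a fluid slab
#'
#' Complex pressure transmission coefficient of a three-medium
#' outer/slab/outer stack at normal incidence,
#' \deqn{t = \frac{2Z}{2Z\cos(k_s d) + i(Z^2+1)\sin(k_s d)}}
#' with \eqn{Z = Z_{slab}/Z_{outer}} and \eqn{k_s d} the slab phase.
#' The coefficient relates the transmitted wave at the exit face to the
#' incident wave at the entry face, so an impedance-matched slab gives
#' the pure delay \eqn{e^{-ik_s d}} and \eqn{|t| \le 1} always, with
#' equality iff matched.
#'
#' @param layer a [skull_layer()] (any slab: medium + thickness).
#' @param frequency Hz.
#' @param outer surrounding [medium()] (water).
#' @return complex scalar transmission factor.
#' @export
skull_transmission <- function(layer, frequency,
                               outer = media_registry()$water) {
  stopifnot(inherits(layer, "skull_layer"))
  check_positive(frequency, "frequency")
  slab_transmission_factor(layer$medium, layer$thickness, frequency, outer)
}

# Shared slab kernel (also used for partial thickness inside the slab).
slab_transmission_factor <- function(slab_medium, thickness, frequency,
                                     outer) {
  Z <- acoustic_impedance(slab_medium) / acoustic_impedance(outer)
  ks <- wavenumber(slab_medium, frequency)
  ph <- ks * thickness
  2 * Z / (2 * Z * cos(ph) + 1i * (Z^2 + 1) * sin(ph))
}

#' Record a hologram by time reversal
#'
#' Propagates the virtual-source cloud (placed at the desired foci)
#' back to the holographic plane with [rs_propagate()], multiplies by
#' the skull-slab transmission factor when a layer sits between foci
#' and plane, and captures the complex pressure and its phase.  The
#' returned hologram is *not* yet conjugated; [conjugate()] flips it
#' into the emission phase the lens must impose.
#'
#' @param sources a [make_virtual_sources()] set.
#' @param layer a [skull_layer()] or `NULL` for free water.
#' @param plane recording [planar_grid()]; must not intersect the slab.
#' @param medium propagation [medium()] (water).
#' @param frequency Hz.
#' @return object of class `"hologram"`: `plane`, `pressure`
#'   ([pressure_field()]), `phase` ([phase_of()]), `conjugated = FALSE`.
#' @export
record_hologram <- function(sources, layer, plane, medium, frequency) {
  stopifnot(inherits(sources, "virtual_sources"),
            inherits(plane, "planar_grid"))
  pts <- grid_points(plane)
  if (!is.null(layer)) {
    stopifnot(inherits(layer, "skull_layer"))
    z0 <- layer$z_entry; z1 <- layer$z_entry + layer$thickness
    if (any(pts[, 3] > z0 - 1e-12 & pts[, 3] < z1 + 1e-12)) {
      stop("recording plane intersects the skull slab", call. = FALSE)
    }
  }
  p <- rs_propagate(sources$positions, sources$strengths, pts, medium,
                    frequency, eps = plane$spacing / 10)
  if (!is.null(layer)) p <- p * skull_transmission(layer, frequency, medium)
  pf <- pressure_field(plane, p, frequency)
  structure(list(plane = plane, pressure = pf, phase = phase_of(pf),
                 conjugated = FALSE, layer = layer),
            class = "hologram")
}

#' Phase-conjugate a hologram
#'
#' Time-reversal emission: negate the recorded phase (conjugate the
#' complex pressure) so that re-emitting from the plane refocuses at
#' the virtual sources.  Magnitudes are preserved.  Conjugating an
#' already-conjugated hologram is an error unless `force = TRUE` (the
#' involution is then an identity on phases).
#'
#' @param hologram a [record_hologram()] result.
#' @param force allow double conjugation.
#' @return the conjugated hologram (`conjugated = TRUE`).
#' @export
conjugate <- function(hologram, force = FALSE) {
  stopifnot(inherits(hologram, "hologram"))
  if (hologram$conjugated && !force) {
    stop("hologram is already conjugated (use force = TRUE to invert back)",
         call. = FALSE)
  }
  pf <- hologram$pressure
  pf$values <- Conj(pf$values)
  hologram$pressure <- pf
  # negate-and-rewrap (rather than Arg(conj)) so the branch point -pi
  # lands on the +pi side of the (-pi, pi] convention
  hologram$phase$values <- wrap_phase(-hologram$phase$values)
  hologram$conjugated <- !hologram$conjugated
  hologram
}

#' @export
print.hologram <- function(x, ...) {
  cat(sprintf("<hologram> %d x %d plane at %g MHz, %sconjugated\n",
              x$plane$shape[1], x$plane$shape[2],
              x$pressure$frequency / 1e6,
              if (x$conjugated) "" else "not "))
  invisible(x)
}
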