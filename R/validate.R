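#' Forward-simulate the transmitted field of a lens
#'
#' Sends a unit-amplitude plane wave through the lens: each pixel
#' transmits its [slab_T()] coefficient, the exit plane is discretised
#' into Huygens secondary sources at <= lambda/4 pitch (at least 2 x 2
#' per pixel; a 0.25 mm pixel is lambda/2 in water at 3 MHz, so coarser
#' sampling aliases), and the sources are propagated one-way into the
#' evaluation grid with [rs_propagate()].  Points beyond the skull slab
#' are multiplied by its transmission factor (partial thickness for
#' points inside the slab).  Multiple lens-skull reflections are
#' neglected: this is a one-way semi-analytic substitute for a full FEM
#' solve, validated against closed-form oracles and the designed focal
#' geometry.
#'
#' @param map a [design_height_map()] / [quantize_heights()] result.
#' @param layer a [skull_layer()] or `NULL`.
#' @param grid evaluation [volume_grid()], strictly downstream of the
#'   lens exit plane (all z > 0).
#' @param frequency Hz.
#' @param subsample Huygens sources per pixel edge; default is the
#'   lambda/4 rule (at least 2).  Raise for extreme near-field work.
#' @return a [pressure_field()] on `grid`.
#' @export
simulate_field <- function(map, layer, grid, frequency, subsample = NULL) {
  stopifnot(inherits(map, "height_map"), inherits(grid, "volume_grid"))
  if (!is.null(layer)) stopifnot(inherits(layer, "skull_layer"))
  if (min(grid$z) <= 0) {
    stop("evaluation grid overlaps the lens body (needs z > 0)",
         call. = FALSE)
  }
  spec <- map$spec
  outer_m <- spec$outer_medium
  lam <- outer_m$c_long / frequency
  s <- if (is.null(subsample)) {
    max(2L, as.integer(ceiling(spec$pixel_width / (lam / 4))))
  } else {
    as.integer(subsample)
  }
  src <- huygens_sources(map, frequency, s)
  pts <- grid_points(grid)
  p <- rs_propagate(src$pos, src$strengths, pts, outer_m, frequency,
                    eps = min(grid$spacing) / 10)
  if (!is.null(layer)) {
    p <- p * skull_factor_at(pts[, 3], layer, frequency, outer_m)
  }
  pressure_field(grid, p, frequency)
}

# Exit-plane Huygens sources for a unit incident plane wave:
# strength = T(h_pixel) / (rho0 c0) * sub-cell area  (u0 * dS).
huygens_sources <- function(map, frequency, s) {
  spec <- map$spec
  npx <- spec$n_pixels
  dw <- spec$pixel_width
  dsub <- dw / s
  Tpx <- slab_T(as.vector(map$heights), spec, frequency)
  # pixel centre coordinates (aperture centred on the axis)
  cx <- (seq_len(npx[1]) - (npx[1] + 1) / 2) * dw
  cy <- (seq_len(npx[2]) - (npx[2] + 1) / 2) * dw
  off <- (seq_len(s) - (s + 1) / 2) * dsub
  # full sub-lattice: for each pixel (x fastest, matching the heights
  # matrix layout), s*s sub-sources
  px <- rep(cx, times = npx[2])
  py <- rep(cy, each = npx[1])
  ox <- rep(rep(off, each = 1L), times = s)          # s*s x-offsets
  oy <- rep(off, each = s)
  pos <- cbind(
    x = rep(px, each = s * s) + rep(ox, times = length(px)),
    y = rep(py, each = s * s) + rep(oy, times = length(py)),
    z = 0
  )
  z0 <- acoustic_impedance(spec$outer_medium)
  strengths <- rep(Tpx, each = s * s) * dsub^2 / z0
  list(pos = pos, strengths = strengths, n_sub = s)
}

# Per-point skull factor as a function of axial position.
skull_factor_at <- function(z, layer, frequency, outer) {
  z0 <- layer$z_entry; z1 <- z0 + layer$thickness
  fac <- rep(complex(real = 1), length(z))
  beyond <- z >= z1
  if (any(beyond)) {
    fac[beyond] <- skull_transmission(layer, frequency, outer)
  }
  inside <- z > z0 & z < z1
  if (any(inside)) {
    fac[inside] <- vapply(z[inside] - z0, function(d) {
      slab_transmission_factor(layer$medium, d, frequency, outer)
    }, complex(1))
  }
  fac
}

#' Re-emit a conjugated hologram and propagate it forward
#'
#' Phase-conjugate emission without any lens or skull: every plane
#' sample radiates with unit magnitude and the hologram's (conjugated)
#' phase.  By the time-reversal property the field refocuses at the
#' original virtual-source positions; used to verify recordings
#' independently of the lens inversion.
#'
#' @param hologram a conjugated hologram.
#' @param grid evaluation [volume_grid()] (z > 0).
#' @param medium propagation [medium()].
#' @param frequency Hz.
#' @return a [pressure_field()] on `grid`.
#' @export
refocus_field <- function(hologram, grid, medium, frequency) {
  stopifnot(inherits(hologram, "hologram"), inherits(grid, "volume_grid"))
  if (!hologram$conjugated) {
    stop("hologram must be conjugated before emission", call. = FALSE)
  }
  if (min(grid$z) <= 0) {
    stop("evaluation grid must lie downstream of the plane (z > 0)",
         call. = FALSE)
  }
  plane <- hologram$plane
  dS <- plane$spacing^2
  z0 <- acoustic_impedance(medium)
  strengths <- exp(complex(imaginary = hologram$phase$values)) * dS / z0
  p <- rs_propagate(grid_points(plane), strengths, grid_points(grid),
                    medium, frequency, eps = min(grid$spacing) / 10)
  pressure_field(grid, p, frequency)
}

#' Locate focal peaks in a simulated field
#'
#' Finds the `n` largest local maxima of |p| on the grid (26-neighbour
#' local maxima, at least one grid cell apart), refines each position
#' by a per-axis quadratic fit through the three samples around the
#' peak, and reports amplitudes normalised to the global maximum plus
#' lateral (x) and axial (z) full widths at half maximum.
#'
#' @param field a [pressure_field()] on a [volume_grid()].
#' @param n number of peaks requested, >= 1.
#' @return object of class `"focal_report"`: `peaks` (data.frame with
#'   x, y, z in metres, `amplitude`, `fwhm_lateral`, `fwhm_axial`) and
#'   `symmetry_error` (relative amplitude difference of the two
#'   strongest peaks; `NA` for n < 2).
#' @export
find_foci <- function(field, n) {
  stopifnot(inherits(field, "pressure_field"),
            inherits(field$grid, "volume_grid"))
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be >= 1", call. = FALSE)
  g <- field$grid
  a <- array(Mod(field$values), g$shape)
  cand <- local_maxima(a)
  if (nrow(cand) < n) {
    stop(sprintf("insufficient peaks: found %d local maxima, requested %d",
                 nrow(cand), n), call. = FALSE)
  }
  cand <- cand[order(-cand[, "value"]), , drop = FALSE]
  sel <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (length(sel) == n) break
    ok <- all(vapply(sel, function(j) {
      max(abs(cand[i, 1:3] - cand[j, 1:3])) > 1L
    }, logical(1)))
    if (ok) sel <- c(sel, i)
  }
  if (length(sel) < n) {
    stop(sprintf("insufficient peaks: only %d maxima with >= 1-cell separation",
                 length(sel)), call. = FALSE)
  }
  cand <- cand[sel, , drop = FALSE]
  coords <- list(g$x, g$y, g$z)
  peaks <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i) {
    ijk <- cand[i, 1:3]
    pos <- numeric(3)
    for (d in 1:3) {
      cc <- coords[[d]]
      pos[d] <- cc[ijk[d]]
      if (ijk[d] > 1L && ijk[d] < length(cc)) {
        idx <- ijk; f <- numeric(3)
        for (m in -1:1) { idx[d] <- ijk[d] + m; f[m + 2] <- a[matrix(idx, 1)] }
        den <- f[1] - 2 * f[2] + f[3]
        if (den < 0) {
          delta <- 0.5 * (f[1] - f[3]) / den
          pos[d] <- pos[d] + max(-0.5, min(0.5, delta)) * g$spacing[d]
        }
      }
    }
    data.frame(x = pos[1], y = pos[2], z = pos[3],
               amplitude = cand[i, "value"])
  }))
  pmax_all <- max(a)
  peaks$amplitude <- peaks$amplitude / pmax_all
  peaks$fwhm_lateral <- vapply(seq_len(nrow(cand)), function(i)
    fwhm_along(a, coords, cand[i, 1:3], 1L), numeric(1))
  peaks$fwhm_axial <- vapply(seq_len(nrow(cand)), function(i)
    fwhm_along(a, coords, cand[i, 1:3], 3L), numeric(1))
  sym <- NA_real_
  if (n >= 2L) {
    amps <- sort(peaks$amplitude, decreasing = TRUE)[1:2]
    sym <- (amps[1] - amps[2]) / amps[1]
  }
  structure(list(peaks = peaks, symmetry_error = sym, n = n),
            class = "focal_report")
}

# indices + values of strict 26-neighbour local maxima (boundaries in
# dimensions of size 1 are ignored; other boundaries are excluded).
local_maxima <- function(a) {
  dm <- dim(a)
  idx <- which(array(TRUE, dm))
  ijk <- arrayInd(idx, dm)
  keep <- rep(TRUE, length(idx))
  for (d in 1:3) {
    if (dm[d] > 1L) keep <- keep & ijk[, d] > 1L & ijk[, d] < dm[d]
  }
  cand <- which(keep)
  shifts <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  shifts <- shifts[rowSums(abs(shifts)) > 0, , drop = FALSE]
  shifts <- shifts[apply(shifts, 1L, function(s)
    all(dm > 1L | s == 0L)), , drop = FALSE]
  is_max <- rep(TRUE, length(cand))
  v0 <- a[cand]
  for (r in seq_len(nrow(shifts))) {
    nb <- ijk[cand, , drop = FALSE]
    nb[, 1] <- nb[, 1] + shifts[r, 1]
    nb[, 2] <- nb[, 2] + shifts[r, 2]
    nb[, 3] <- nb[, 3] + shifts[r, 3]
    is_max <- is_max & v0 > a[nb]
  }
  out <- cbind(ijk[cand[is_max], , drop = FALSE], value = v0[is_max])
  colnames(out) <- c("i", "j", "k", "value")
  out
}

# FWHM of |p| along grid axis `d` through cell `ijk`; NA when a half-max
# crossing is not bracketed inside the grid.
fwhm_along <- function(a, coords, ijk, d) {
  idx <- as.list(ijk)
  prof <- switch(d,
                 a[, ijk[2], ijk[3]],
                 a[ijk[1], , ijk[3]],
                 a[ijk[1], ijk[2], ])
  cc <- coords[[d]]
  i0 <- ijk[d]
  half <- prof[i0] / 2
  cross <- function(ii) {
    # linear interpolation of the half-max coordinate between ii, ii+1
    cc[ii] + (half - prof[ii]) / (prof[ii + 1] - prof[ii]) *
      (cc[ii + 1] - cc[ii])
  }
  left <- NA_real_
  if (i0 > 1L) {
    for (ii in seq(i0 - 1L, 1L, by = -1L)) {
      if (prof[ii] <= half) { left <- cross(ii); break }
    }
  }
  right <- NA_real_
  if (i0 < length(prof)) {
    for (ii in seq(i0, length(prof) - 1L)) {
      if (prof[ii + 1L] <= half) { right <- cross(ii); break }
    }
  }
  right - left
}

#' @export
print.focal_report <- function(x, ...) {
  cat(sprintf("<focal_report> %d peak(s)\n", nrow(x$peaks)))
  p <- x$peaks
  for (i in seq_len(nrow(p))) {
    cat(sprintf(
      "  (%+.3f, %+.3f, %+.3f) mm  amp %.3f  FWHM lat %.3f / ax %.3f mm\n",
      p$x[i] * 1e3, p$y[i] * 1e3, p$z[i] * 1e3, p$amplitude[i],
      p$fwhm_lateral[i] * 1e3, p$fwhm_axial[i] * 1e3))
  }
  if (!is.na(x$symmetry_error)) {
    cat(sprintf("  bilateral symmetry error: %.2f%%\n",
                100 * x$symmetry_error))
  }
  invisible(x)
}

#' Normalised pressure magnitude along an axis-aligned line
#'
#' Trilinear interpolation of |p| along a line parallel to one grid
#' axis, normalised to the global field maximum.
#'
#' @param field a [pressure_field()] on a [volume_grid()].
#' @param axis `"x"`, `"y"` or `"z"`: the direction of the line.
#' @param at named numeric of the two fixed coordinates, metres (e.g.
#'   `c(x = 1.5e-3, y = 0)` for an axial line).
#' @param range numeric length-2 extent along `axis`, metres; defaults
#'   to the grid extent.
#' @param n samples along the line.
#' @return object of class `"line_profile"`: data.frame with
#'   `coordinate` (m) and `amplitude` (normalised, in `[0, 1]`).
#' @export
line_profile <- function(field, axis, at, range = NULL, n = 201L) {
  stopifnot(inherits(field, "pressure_field"),
            inherits(field$grid, "volume_grid"))
  axis <- match.arg(axis, c("x", "y", "z"))
  g <- field$grid
  if (is.null(range)) range <- range(g[[axis]])
  coord <- seq(range[1], range[2], length.out = n)
  pts <- matrix(0, n, 3L, dimnames = list(NULL, c("x", "y", "z")))
  pts[, axis] <- coord
  for (nm in setdiff(c("x", "y", "z"), axis)) {
    if (!nm %in% names(at)) {
      stop(sprintf("`at` must fix coordinate '%s'", nm), call. = FALSE)
    }
    pts[, nm] <- at[[nm]]
  }
  amp <- interp_field_mod(field, pts)
  structure(list(profile = data.frame(coordinate = coord,
                                      amplitude = amp / max(Mod(field$values))),
                 axis = axis, at = at),
            class = "line_profile")
}

# trilinear interpolation of |p| at arbitrary points; errors outside grid
interp_field_mod <- function(field, pts) {
  g <- field$grid
  a <- array(Mod(field$values), g$shape)
  loc <- function(cc, x) {
    if (any(x < min(cc) - 1e-12 | x > max(cc) + 1e-12)) {
      stop("line lies outside the field grid", call. = FALSE)
    }
    if (length(cc) == 1L) {
      return(list(i = rep(1L, length(x)), w = rep(0, length(x))))
    }
    i <- findInterval(x, cc, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), length(cc) - 1L)
    list(i = i, w = (x - cc[i]) / (cc[i + 1] - cc[i]))
  }
  lx <- loc(g$x, pts[, 1]); ly <- loc(g$y, pts[, 2]); lz <- loc(g$z, pts[, 3])
  nx <- g$shape[1]; ny <- g$shape[2]
  val <- numeric(nrow(pts))
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    ix <- pmin(lx$i + cx, g$shape[1]); iy <- pmin(ly$i + cy, g$shape[2])
    iz <- pmin(lz$i + cz, g$shape[3])
    w <- (ifelse(cx == 1, lx$w, 1 - lx$w)) *
      (ifelse(cy == 1, ly$w, 1 - ly$w)) *
      (ifelse(cz == 1, lz$w, 1 - lz$w))
    val <- val + w * a[cbind(ix, iy, iz)]
  }
  val
}

#' Focal robustness across skull thickness
#'
#' Re-simulates a fixed lens design through skull slabs of the given
#' thicknesses (the design is *not* re-derived per thickness) and
#' extracts the focal report for each — the computational analogue of
#' sweeping skulls of different ages under one printed lens.
#'
#' @param map the fixed [quantize_heights()] design.
#' @param layer template [skull_layer()] (medium and standoff reused).
#' @param thicknesses numeric vector of slab thicknesses, metres.
#' @param grid evaluation [volume_grid()].
#' @param frequency Hz.
#' @param n peaks per report.
#' @return named list of [find_foci()] reports, one per thickness
#'   (names in micrometres).
#' @export
thickness_sweep <- function(map, layer, thicknesses, grid, frequency,
                            n = 2L) {
  stopifnot(inherits(layer, "skull_layer"))
  if (length(thicknesses) == 0L) return(structure(list(), names = character()))
  stopifnot(all(thicknesses > 0))
  out <- lapply(thicknesses, function(th) {
    ly <- skull_layer(layer$medium, th, layer$z_entry)
    find_foci(simulate_field(map, ly, grid, frequency), n)
  })
  names(out) <- sprintf("%g", thicknesses * 1e6)
  out
}

#' Correlation between two field magnitudes
#'
#' Pearson correlation of |p| over two fields sampled on congruent
#' grids; 1 for identical (or rescaled) fields, ~0 for unrelated ones.
#'
#' @param a,b [pressure_field()]s on identical grids.
#' @return correlation in `[-1, 1]`.
#' @export
field_correlation <- function(a, b) {
  stopifnot(inherits(a, "pressure_field"), inherits(b, "pressure_field"))
  if (!isTRUE(all.equal(a$grid, b$grid))) {
    stop("fields are not on congruent grids", call. = FALSE)
  }
  stats::cor(Mod(a$values), Mod(b$values))
}
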