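#' Planar sampling grid
#'
#' A regular lattice of sample points on a plane, used for the
#' holographic (recording/emission) plane.  The grid is centred on
#' `center` and spanned by two orthonormal axis vectors; the default
#' axes give an x-y plane at constant z.
#'
#' @param center numeric length-3, plane centre (x, y, z), metres.
#' @param shape integer length-2, samples along each axis `(nx, ny)`.
#' @param spacing sample pitch, metres.
#' @param u,v orthonormal in-plane axis vectors.
#' @return object of class `"planar_grid"`.
#' @examples
#' g <- planar_grid(shape = c(4, 4), spacing = 0.25e-3)
#' head(grid_points(g))
#' @export
planar_grid <- function(center = c(0, 0, 0), shape, spacing,
                        u = c(1, 0, 0), v = c(0, 1, 0)) {
  check_positive(spacing, "spacing")
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2L, all(shape >= 1L), length(center) == 3L)
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  if (abs(sum(u * v)) > 1e-12) {
    stop("plane axes `u` and `v` must be orthogonal", call. = FALSE)
  }
  structure(
    list(center = as.numeric(center), shape = shape, spacing = spacing,
         u = u, v = v),
    class = "planar_grid"
  )
}

#' Volumetric sampling grid
#'
#' Axis-aligned regular 3D lattice used as the field-evaluation region.
#'
#' @param xlim,ylim,zlim numeric length-2 extents, metres.  A degenerate
#'   extent (equal limits) yields a single sample along that axis.
#' @param spacing scalar or length-3 sample pitch `(dx, dy, dz)`, metres.
#' @return object of class `"volume_grid"` with coordinate vectors
#'   `x`, `y`, `z` and `shape = c(nx, ny, nz)`.
#' @examples
#' volume_grid(c(-1e-3, 1e-3), c(0, 0), c(2e-3, 4e-3), 0.5e-3)
#' @export
volume_grid <- function(xlim, ylim, zlim, spacing) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  ax <- function(lim, d) {
    stopifnot(length(lim) == 2L, lim[2] >= lim[1])
    if (lim[2] == lim[1]) return(lim[1])
    seq(lim[1], lim[2], by = d)
  }
  x <- ax(xlim, spacing[1]); y <- ax(ylim, spacing[2]); z <- ax(zlim, spacing[3])
  structure(
    list(x = x, y = y, z = z, spacing = spacing,
         shape = c(length(x), length(y), length(z))),
    class = "volume_grid"
  )
}

#' Cartesian coordinates of every grid sample
#'
#' @param grid a [planar_grid()] or [volume_grid()].
#' @return numeric matrix with one row per sample and columns x, y, z
#'   (metres).  The first grid axis varies fastest, matching how field
#'   values are stored.
#' @export
grid_points <- function(grid) {
  if (inherits(grid, "planar_grid")) {
    nx <- grid$shape[1]; ny <- grid$shape[2]; d <- grid$spacing
    iu <- (seq_len(nx) - (nx + 1) / 2) * d
    iv <- (seq_len(ny) - (ny + 1) / 2) * d
    off_u <- rep(iu, times = ny)
    off_v <- rep(iv, each = nx)
    pts <- cbind(
      grid$center[1] + off_u * grid$u[1] + off_v * grid$v[1],
      grid$center[2] + off_u * grid$u[2] + off_v * grid$v[2],
      grid$center[3] + off_u * grid$u[3] + off_v * grid$v[3]
    )
  } else if (inherits(grid, "volume_grid")) {
    pts <- as.matrix(expand.grid(x = grid$x, y = grid$y, z = grid$z,
                                 KEEP.OUT.ATTRS = FALSE))
  } else {
    stop("`grid` must be a planar_grid or volume_grid", call. = FALSE)
  }
  dimnames(pts) <- list(NULL, c("x", "y", "z"))
  pts
}

n_points <- function(grid) prod(grid$shape)

#' Complex monochromatic pressure field
#'
#' Container pairing a sampling grid with complex pressure values and
#' the single frequency they were computed at.
#'
#' @param grid a [planar_grid()] or [volume_grid()].
#' @param values complex vector, Pa, one per grid sample (first grid
#'   axis fastest).
#' @param frequency Hz, positive.
#' @return object of class `"pressure_field"`.
#' @export
pressure_field <- function(grid, values, frequency) {
  stopifnot(inherits(grid, "planar_grid") || inherits(grid, "volume_grid"))
  check_positive(frequency, "frequency")
  values <- as.complex(values)
  if (length(values) != n_points(grid)) {
    stop("`values` length does not match the grid", call. = FALSE)
  }
  if (any(!is.finite(Re(values)) | !is.finite(Im(values)))) {
    stop("pressure values must be finite", call. = FALSE)
  }
  structure(list(grid = grid, values = values, frequency = frequency),
            class = "pressure_field")
}

#' @export
print.pressure_field <- function(x, ...) {
  cat(sprintf("<pressure_field> %s samples at %g MHz, max |p| = %.4g Pa\n",
              paste(x$grid$shape, collapse = " x "), x$frequency / 1e6,
              max(Mod(x$values))))
  invisible(x)
}

#' Phase map of a complex pressure field
#'
#' Full-circle argument of the pressure, `atan2(Im p, Re p)`, wrapped to
#' `(-pi, pi]`.  Samples with exactly zero magnitude map to phase 0 by
#' convention (the argument is undefined there).
#'
#' @param field a [pressure_field()].
#' @return object of class `"phase_map"`: the grid plus `values` in
#'   radians, all in `(-pi, pi]`.
#' @examples
#' g <- planar_grid(shape = c(1, 1), spacing = 1e-3)
#' phase_of(pressure_field(g, complex(real = -1, imaginary = -1), 1e6))$values
#' @export
phase_of <- function(field) {
  stopifnot(inherits(field, "pressure_field"))
  ph <- Arg(field$values)          # Arg() already returns (-pi, pi]
  ph[Mod(field$values) == 0] <- 0
  structure(list(grid = field$grid, values = ph), class = "phase_map")
}
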