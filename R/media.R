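#' Acoustic medium
#'
#' A homogeneous, lossless acoustic medium characterised by its density
#' and longitudinal sound speed.  A transversal (shear) speed may be
#' recorded for solids such as skull bone or cured resin, but bulk
#' propagation in this package is fluid-like: only the longitudinal
#' branch is used (a documented limitation for the thin, near-normal-
#' incidence skull layer it models).
#'
#' @param name character label.
#' @param density mass density, kg/m^3.
#' @param c_long longitudinal sound speed, m/s.
#' @param c_shear transversal sound speed, m/s, or `NA` for fluids.
#' @return an object of class `"medium"`.
#' @examples
#' water <- medium("water", 1000, 1500)
#' wavenumber(water, 3e6)
#' @seealso [media_registry()], [wavenumber()], [acoustic_impedance()]
#' @export
medium <- function(name, density, c_long, c_shear = NA_real_) {
  check_positive(density, "density")
  check_positive(c_long, "c_long")
  if (!is.na(c_shear)) check_nonnegative(c_shear, "c_shear")
  structure(
    list(name = as.character(name)[1L], density = density,
         c_long = c_long, c_shear = c_shear),
    class = "medium"
  )
}

#' @export
print.medium <- function(x, ...) {
  cat(sprintf("<medium> %s: rho = %g kg/m^3, c_long = %g m/s%s\n",
              x$name, x$density, x$c_long,
              if (is.na(x$c_shear)) "" else sprintf(", c_shear = %g m/s",
                                                    x$c_shear)))
  invisible(x)
}

#' Built-in media registry
#'
#' Acoustic properties of the three media of the mouse transcranial
#' lens problem: degassed water, the stereolithography resin the lens
#' is printed from, and mouse skull bone.
#'
#' @return named list of [medium()] objects (`water`, `lens`, `skull`).
#' @examples
#' media_registry()$skull
#' @export
media_registry <- function() {
  list(
    water = medium("water", 1000, 1500),
    lens  = medium("lens",  1180, 2700, 1160),
    skull = medium("skull", 1912, 2300, 1626)
  )
}

#' Acoustic wavenumber
#'
#' `k = 2 pi f / c` using the longitudinal sound speed of the medium.
#'
#' @param medium a [medium()].
#' @param frequency Hz, positive.
#' @return wavenumber, rad/m.
#' @examples
#' wavenumber(medium("water", 1000, 1500), 3e6)  # 4000*pi
#' @export
wavenumber <- function(medium, frequency) {
  stopifnot(inherits(medium, "medium"))
  check_positive(frequency, "frequency")
  2 * pi * frequency / medium$c_long
}

#' Characteristic acoustic impedance
#'
#' `Z = rho * c_long`, Pa s/m (rayl).
#'
#' @inheritParams wavenumber
#' @return impedance, rayl.
#' @export
acoustic_impedance <- function(medium) {
  stopifnot(inherits(medium, "medium"))
  medium$density * medium$c_long
}
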