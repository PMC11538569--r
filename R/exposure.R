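#' Stimulation pulse scheme
#'
#' Timing hierarchy of the pulsed-ultrasound stimulation waveform:
#' carrier bursts at the fundamental frequency, repeated at the pulse
#' repetition frequency, gated into sonication-on periods separated by
#' interstimulus intervals.
#'
#' @param ff fundamental frequency, Hz (default 3 MHz).
#' @param prf pulse repetition frequency, Hz (500).
#' @param tbd tone-burst duration, s (0.4 ms); must satisfy
#'   `tbd <= 1/prf`.
#' @param sd sonication duration, s (1).
#' @param isi interstimulus interval, s (4).
#' @param session daily session length, s (20 min).
#' @return object of class `"pulse_scheme"`.
#' @examples
#' duty_cycle(pulse_scheme()$tbd, pulse_scheme()$prf)  # 0.2
#' @export
pulse_scheme <- function(ff = 3e6, prf = 500, tbd = 0.4e-3,
                         sd = 1, isi = 4, session = 20 * 60) {
  check_positive(ff, "ff"); check_positive(prf, "prf")
  check_nonnegative(tbd, "tbd")
  check_nonnegative(sd, "sd"); check_nonnegative(isi, "isi")
  check_positive(session, "session")
  if (tbd > 1 / prf + 1e-15) {
    stop("`tbd` must not exceed the pulse period 1/prf", call. = FALSE)
  }
  structure(list(ff = ff, prf = prf, tbd = tbd, sd = sd, isi = isi,
                 session = session),
            class = "pulse_scheme")
}

#' Intra-burst duty cycle
#'
#' Fraction of each pulse period the carrier is on: `tbd * prf`.
#'
#' @param tbd tone-burst duration, s.
#' @param prf pulse repetition frequency, Hz.
#' @return duty cycle in `[0, 1]`.
#' @examples
#' duty_cycle(0.4e-3, 500)  # 0.2
#' @export
duty_cycle <- function(tbd, prf) {
  check_positive(prf, "prf"); check_nonnegative(tbd, "tbd")
  if (tbd > 1 / prf + 1e-15) {
    stop("`tbd` must not exceed the pulse period 1/prf", call. = FALSE)
  }
  tbd * prf
}

#' Session-level effective duty
#'
#' Intra-burst duty further scaled by the sonication-on fraction of the
#' stimulus cycle: `dc * sd / (sd + isi)`.
#'
#' @param dc intra-burst duty cycle, fraction.
#' @param sd sonication duration, s.
#' @param isi interstimulus interval, s.
#' @return effective duty in `[0, 1]`.
#' @export
effective_duty <- function(dc, sd, isi) {
  stopifnot(dc >= 0, dc <= 1, sd >= 0, isi >= 0)
  if (sd + isi <= 0) stop("`sd + isi` must be positive", call. = FALSE)
  dc * sd / (sd + isi)
}

#' Temporal-average from pulse-average intensity
#'
#' `Ispta = Isppa * duty`: the spatial-peak temporal-average intensity
#' given the pulse-average intensity and a temporal duty factor.
#'
#' @param isppa spatial-peak pulse-average intensity, W/cm^2.
#' @param duty temporal duty factor in `[0, 1]`.
#' @return Ispta, W/cm^2.
#' @export
ispta_from_isppa <- function(isppa, duty) {
  stopifnot(isppa >= 0, duty >= 0, duty <= 1)
  isppa * duty
}

#' Mechanical index
#'
#' `MI = pnp / sqrt(ff)` with the peak negative pressure in MPa and the
#' fundamental frequency in MHz (the standard regulatory definition;
#' unit coercion is the caller's responsibility and deliberately
#' explicit).
#'
#' @param pnp peak negative pressure, MPa.
#' @param ff fundamental frequency, MHz.
#' @return mechanical index, unitless.
#' @examples
#' mechanical_index(0.5 * sqrt(3), 3)  # 0.5
#' @export
mechanical_index <- function(pnp, ff) {
  check_positive(ff, "ff (MHz)")
  stopifnot(pnp >= 0)
  pnp / sqrt(ff)
}

#' Check exposure indices against regulatory limits
#'
#' Pass/fail flags per index; a value exactly at its limit passes.
#' Defaults are the diagnostic-ultrasound track limits MI 1.9 and
#' Ispta 0.72 W/cm^2, overridable per call.
#'
#' @param mi mechanical index (or `NA`).
#' @param ispta temporal-average intensity, W/cm^2 (or `NA`).
#' @param limits named list with `mi_max` and `ispta_max`, positive.
#' @return named logical vector (`mi`, `ispta`); `NA` where the value
#'   was not supplied.
#' @export
limit_check <- function(mi, ispta,
                        limits = list(mi_max = 1.9, ispta_max = 0.72)) {
  check_positive(limits$mi_max, "mi_max")
  check_positive(limits$ispta_max, "ispta_max")
  c(mi = if (is.na(mi)) NA else mi <= limits$mi_max,
    ispta = if (is.na(ispta)) NA else ispta <= limits$ispta_max)
}

#' Exposure report for a pulse scheme
#'
#' Collects the duty factors, intensities and safety indices of a
#' stimulation scheme.  `ispta` uses the intra-burst duty cycle (the
#' convention under which a 0.9 W/cm^2 pulse-average at 20% duty gives
#' 180 mW/cm^2); `ispta_effective` additionally folds in the
#' sonication/interval gating — both are reported side by side since
#' either convention appears in the literature.
#'
#' @param scheme a [pulse_scheme()].
#' @param isppa spatial-peak pulse-average intensity, W/cm^2, or `NA`.
#' @param pnp peak negative pressure, MPa, or `NA`.
#' @param limits see [limit_check()].
#' @return object of class `"exposure_report"`.
#' @examples
#' exposure_report(pulse_scheme(), isppa = 0.9, pnp = 0.5 * sqrt(3))
#' @export
exposure_report <- function(scheme, isppa = NA_real_, pnp = NA_real_,
                            limits = list(mi_max = 1.9, ispta_max = 0.72)) {
  stopifnot(inherits(scheme, "pulse_scheme"))
  dc <- duty_cycle(scheme$tbd, scheme$prf)
  ed <- effective_duty(dc, scheme$sd, scheme$isi)
  ispta <- if (is.na(isppa)) NA_real_ else ispta_from_isppa(isppa, dc)
  ispta_eff <- if (is.na(isppa)) NA_real_ else ispta_from_isppa(isppa, ed)
  mi <- if (is.na(pnp)) NA_real_ else mechanical_index(pnp, scheme$ff / 1e6)
  structure(list(scheme = scheme, duty_cycle = dc, effective_duty = ed,
                 isppa = isppa, ispta = ispta, ispta_effective = ispta_eff,
                 mi = mi,
                 limit_flags = limit_check(mi, ispta, limits),
                 limits = limits),
            class = "exposure_report")
}

#' @export
print.exposure_report <- function(x, ...) {
  s <- x$scheme
  cat(sprintf("<exposure_report> FF %g MHz, PRF %g Hz, TBD %g ms, SD %g s, ISI %g s\n",
              s$ff / 1e6, s$prf, s$tbd * 1e3, s$sd, s$isi))
  cat(sprintf("  duty cycle %.1f%%  effective duty %.1f%%\n",
              100 * x$duty_cycle, 100 * x$effective_duty))
  if (!is.na(x$isppa)) {
    cat(sprintf("  Isppa %.3g W/cm^2  Ispta %.3g W/cm^2 (burst) / %.3g W/cm^2 (with SD/ISI)\n",
                x$isppa, x$ispta, x$ispta_effective))
  }
  if (!is.na(x$mi)) cat(sprintf("  MI %.3g\n", x$mi))
  fl <- x$limit_flags
  cat(sprintf("  limits: MI <= %g [%s], Ispta <= %g W/cm^2 [%s]\n",
              x$limits$mi_max, flag_str(fl["mi"]),
              x$limits$ispta_max, flag_str(fl["ispta"])))
  invisible(x)
}

flag_str <- function(f) {
  if (is.na(f)) "n/a" else if (f) "pass" else "FAIL"
}
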