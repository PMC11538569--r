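---
title: "Designing multifocal transcranial holographic lenses with holofocus"
author: "holofocus authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing multifocal transcranial holographic lenses with holofocus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holofocus)
```

## The problem

Low-intensity transcranial ultrasound can stimulate deep brain nuclei
noninvasively, but a flat single-element transducer delivers one broad
beam. Disorders such as Parkinsonism involve *circuits* — for a mouse,
the left and right dorsal striatum sit roughly ±1.5 mm off the
midline at ~3.5 mm depth — so a practical wearable stimulator needs
several simultaneous foci from one element. A passive phase plate (an
acoustic hologram) bonded to the transducer face can do this: its
spatially varying thickness imprints a designed phase profile on the
transmitted wave, and diffraction does the rest. `holofocus`
implements the complete design loop for such a lens, including the
phase compensation for the thin mouse skull the beam must cross, a
forward simulator that verifies the resulting field, and the pulse
dosimetry of the stimulation waveform.

## The model

### Propagation

All fields are monochromatic at the working frequency $f$ (3 MHz by
default) with time convention $e^{+i\omega t}$. A radiating surface
with particle velocity $u_0$ produces, at a point $d$,

$$p(d) = \frac{i\omega\rho_0}{2\pi}\int_S u_0(d_0)\,
  \frac{e^{-ik_0|d-d_0|}}{|d-d_0|}\,dS,$$

the Rayleigh–Sommerfeld diffraction integral for a baffled source in
water ($k_0 = \omega/c_0$). `rs_propagate()` evaluates the discrete
midpoint-rule version of this integral: each source carries
$u_0\,dS$ as a complex strength and the kernel is summed directly.
The discretisation is validated against the closed-form on-axis
pressure of a circular piston (`piston_on_axis()`), which the suite
holds to <1 % relative error.

### Time-reversal recording

To design an $N$-focus lens, each desired focus is represented by a
cloud of virtual point sources (100 per focus by default) drawn
uniformly inside a ball of radius 0.25 mm — the scale of the striatal
nucleus — so the focal energy spreads over the target rather than a
diffraction-limited point. A radius of zero gives an ideal point
focus and is used heavily in the tests. Each source is weighted by
`amplitude / n_sources` and by a carrier factor $e^{+ik_0 z_c}$ that
removes the nominal plane-wave arrival phase of its focus (we apply
the factor at the focus centre $z_c$, which keeps the per-focus
strength sum exactly equal to the focus amplitude; applying it
per-source instead would only add sub-wavelength phase noise within
each cloud).

The cloud is propagated *back* to the holographic plane — the lens
exit face at $z = 0$ — through the skull layer, and the complex
pressure is recorded (`record_hologram()`), then phase-conjugated
(`conjugate()`). Emitting the conjugated phase from the plane
refocuses the field at the virtual sources; this is the core
time-reversal property and is asserted to one grid cell in the test
suite at the design geometry (10 mm aperture, foci near 3.5 mm
depth, targets separated by the bilateral 1.5 mm spacing — closer
targets than the diffraction-limited lobe size cannot be resolved by
any lens and are not a meaningful test).

### The skull layer

The mouse skull is modelled as a flat fluid slab at normal incidence:
thickness 250 µm (100–300 µm across ages), longitudinal speed
2300 m/s, density 1912 kg/m³, at a 0.5 mm standoff from the plane.
Its pressure transmission factor is the standard three-medium result

$$t = \frac{2Z}{2Z\cos(k_s d) + i(Z^2+1)\sin(k_s d)},
  \qquad Z = Z_{\mathrm{skull}}/Z_0,$$

verified in the tests against an independent boundary-value solution.
Because the slab is included in the *recording* step, its phase is
conjugated away by the lens — this is the whole point of the
holographic compensation, and we resolve the ambiguity of whether the
recording should include the skull in favour of including it (a
`layer = NULL` mode records in free water). Shear conversion in the
slab is neglected: the layer is ~λ/3 thick and the design geometry is
near normal incidence; this is a documented limitation, and the
consequence is that in this model a thickness change rescales the
transmitted field by one global complex constant, so focal positions
are *exactly* invariant across the 100–300 µm sweep rather than
merely robust.

### From phase to printable heights

The lens surface is divided into square pixels of width
$\Delta w = 0.25$ mm (40 × 40 over the 10 mm aperture). A resin
column of height $h$ on the base slab (thickness $l$, 0.8 mm default)
transmits

$$T(h) = \frac{2Z\,e^{-ik_0[l-h]}}
  {2Z\cos(k_L h) + i(Z^2+1)\sin(k_L h)},$$

with $Z$ now the resin/water impedance ratio and $k_L$ the resin
wavenumber; $|T| \le 1$ always, with unity at $h = 0$ and at resin
half-wave resonances. The relative phase rate
$(k_0 - k_L)/2\pi \approx 0.89$ cycles/mm means ~1.13 mm of height
spans a full $2\pi$; the default height ceiling `h_max = 1.2 mm` adds
margin while `base + h_max` stays within the 2 mm build height.

`design_height_map()` resamples the conjugated hologram onto the
pixel lattice by averaging the complex field over each pixel
footprint (robust to sub-pixel phase gradients, unlike
centre-sampling), then inverts each pixel's target phase by an
exhaustive scan of $\arg T(h)$ in 5 µm steps. A scan is used instead
of root finding because the phase is non-monotone across the slab
resonances; 240 scan values × 1600 pixels is trivial. Ties resolve
to the smallest height. The amplitude ripple of $|T(h)|$
(0.77–1.00 for the resin/water pair) is deliberately ignored in the
inverse step — the design is phase-only — but recorded per pixel for
diagnostics. `quantize_heights()` then rounds to the 100 µm printer
resolution; the worst-pixel phase penalty is bounded by the phase
slope times half the resolution (~0.28 rad) and is recomputed, not
estimated.

### Forward validation

`simulate_field()` sends a unit plane wave through the printed map:
each pixel contributes $T(h)$ at the exit plane, discretised into
Huygens sources at λ/4 pitch (2 × 2 per pixel — the pixel is λ/2 wide
in water, so coarser sampling aliases; a `subsample` argument raises
the density for extreme near-field work, where the λ/4 default is
good to ~1.5 % and 4 per edge restores <1 %). One-way propagation
with no lens–skull multiple reflections replaces the full
finite-element solve at desk scale; it is validated against
closed-form oracles and the designed focal geometry rather than
against FEM itself. `find_foci()` extracts local maxima with
sub-cell quadratic refinement, normalised amplitudes, FWHMs and the
bilateral symmetry error; `line_profile()` and `field_correlation()`
support Fig.-2-style comparisons; `thickness_sweep()` re-simulates a
fixed design across skull thicknesses.

## The bundled design configuration

`bilateral_ds_fixture()` states the bilateral dorsal-striatum design
in full: 3 MHz, the water/resin/skull media above, 10 mm aperture of
0.25 mm pixels, 250 µm skull at 0.5 mm standoff, two unit-amplitude
foci of 100 virtual sources each at (±1.5, 0, 3.5) mm, a recording
plane sampled at 0.125 mm, and an evaluation grid spanning
x ∈ [−2.5, 2.5], y ∈ [−0.5, 0.5], z ∈ [2.5, 5.5] mm at 0.125 mm.
The jitter clouds of the bilateral pair are mirrored in x
(`mirror_x = TRUE`), so the design is exactly symmetric for every
seed: measured asymmetries in the physical experiment come from an
uneven skull, which this flat-slab world deliberately does not
contain, and we prefer the symmetry of the *stated* anatomy over
jitter-realisation noise.

```{r, eval = FALSE}
lens <- design_lens(bilateral_ds_fixture())
lens
field <- predict(lens)                 # through the 250 um skull
find_foci(field, n = 2)
plot(lens)                             # the pixel relief
write_stl(lens$map, "lens.stl")        # for the printer
```

What the generator does *not* emulate: curved or heterogeneous skull,
shear-mode conversion, attenuation, nonlinearity, transducer
apodisation, and the hydrophone averaging of a measurement chain. A
green focal-recovery test therefore establishes that the design
mathematics and its implementation are self-consistent at the stated
geometry — not that a printed lens on a real mouse will reproduce the
field to the same tolerance.

## Pulse scheme and safety indices

The stimulation waveform is a 3 MHz carrier in 0.4 ms tone bursts at
a 500 Hz pulse repetition frequency (duty cycle 20 %), gated 1 s on /
4 s off. `exposure_report()` assembles the duty factors, the
temporal-average intensity $I_{\mathrm{spta}} = I_{\mathrm{sppa}}
\times \mathrm{duty}$, and the mechanical index
$\mathrm{MI} = p_-/\sqrt{f}$ (MPa, MHz). Whether a quoted
$I_{\mathrm{spta}}$ should include the 1 s/4 s gating as well as the
intra-burst duty is convention-dependent, so both numbers are
reported side by side (`ispta` and `ispta_effective`). Default limit
checks use the diagnostic-ultrasound track values MI ≤ 1.9 and
$I_{\mathrm{spta}} \le 0.72$ W/cm², overridable per call; a value
exactly at a limit passes.

```{r}
exposure_report(pulse_scheme(), isppa = 0.9, pnp = 0.5 * sqrt(3))
```

## Numerical choices and degenerate inputs

* **Phase conventions.** $e^{+i\omega t}$ everywhere; outgoing waves
  carry $e^{-ik_0 r}$; phases live in $(-\pi, \pi]$ with the branch
  point $-\pi$ mapped to $+\pi$, and zero-magnitude samples take
  phase 0 by convention (the argument is undefined there).
  Conjugation negates-and-rewraps rather than taking
  $\arg(\bar p)$, so the branch point behaves as the wrap fixed
  point.
* **Singularity guard.** An evaluation point within one tenth of the
  local grid spacing of a source is an error, not a number: the
  $1/r$ kernel has no meaningful discrete value there.
* **Scan defaults.** Height scan step 5 µm (phase granularity
  ~0.03 rad against a ~5.6 rad/mm slope); peak extraction requires
  ≥ 1 grid cell separation between reported maxima and clamps the
  quadratic sub-cell refinement to half a cell.
* **Degenerate geometry.** Grids that touch the lens body (z ≤ 0) or
  a recording plane inside the skull slab are refused with geometry
  errors; `find_foci()` reports how many maxima it *did* find when
  asked for more than exist.
* **Config I/O.** JSON only — the environment provides no R YAML
  parser — with units carried in the key names (`*_mm`, `*_mhz`) and
  converted to SI at parse time, since mixed-unit configuration is
  the dominant user-error source in this kind of tool. Millimetres
  on every user-facing interface, metres internally.

## Known limitations

One-way propagation ignores lens–skull reverberation and scattering;
the fluid-slab skull ignores shear and curvature, which the physical
experiment shows as focal asymmetry; the lens inversion is phase-only
and single-frequency; the printed-material model is geometric only
(no attenuation in the resin). These are exactly the simplifications
under which the design method itself was conceived, so the package
reproduces the method faithfully while inheriting its assumptions.
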