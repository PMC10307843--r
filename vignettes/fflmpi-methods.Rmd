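---
title: "Traveling-FFL projection MPI: the models behind fflmpi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Traveling-FFL projection MPI: the models behind fflmpi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fflmpi)
```

`fflmpi` is a desk-scale twin of a portable, human-sized interventional
magnetic particle imaging (MPI) scanner that encodes 2D projections with a
traveling field-free line (FFL). This vignette explains the physical models
the package implements, the parameters that matter, the numerical and design
choices made where the hardware description leaves the software free, and
what the synthetic experiments can and cannot show about a real scanner.

## Encoding model

Two saddle-coil pairs driven at `f1 = f2 = 60` Hz with a 90 degree phase
shift produce a magnetic traveling wave along the scanner axis `z`. The wave
carries a comb of FFLs (oriented along `y`, the projection axis) with
alternating gradient polarity, spaced `ffl_spacing` apart; the wave advances
one spacing per half period of `f1`, so the FFL polarity that crosses the
field of view (FOV) alternates between consecutive z-passes. A solenoid pair
at `f3 = 2480` Hz deflects the comb sinusoidally along `x` with amplitude
`x_max`. `ffl_spacing` defaults to one FOV length (`fov_z`), which makes
exactly one FFL cross the FOV per half period and yields the four-fold
sub-image redundancy exploited later.

The package models the field locally and analytically rather than through
coil integration: around each FFL the field is quadrupolar, vanishing on the
line and growing linearly with in-plane distance at the operating gradient
`G` (`field_at()` exposes the signed scalar version of this model, a
triangle wave along `z` with slope `±G`). The operating gradient scales
linearly with the CH1/2 current, `G = 0.36 T/m * I_ch12 / 165 A`, i.e.
0.24 T/m at the 110 A operating point and about 0.25 T/m at 70% power. Coil
winding, inductive coupling and Biot-Savart field maps are deliberately out
of scope: the encoding is specified by its effect (a traveling, deflected
FFL), which is what reconstruction needs to know.

The default timing is commensurate: one 50 ms acquisition holds exactly 3
periods of `f1` and 124 periods of `f3` (124 lines), the trajectory repeats
with the acquisition period, and every harmonic sideband `n*f3 + k*f1`
falls exactly on a 20 Hz FFT bin. Sampling defaults to `fs = 496` kS/s
(200 samples per deflection period); what the analysis actually requires is
`fs > 2 * n_max * f3` for the highest retained harmonic and an integer
number of samples per window, both of which are validated. The acquisition
window starts `ramp_time` (default 10 ms) after waveform start so that the
drive amplitudes are settled.

## Signal formation

Tracer voxels respond with the static Langevin magnetization
`L(xi) = coth(xi) - 1/xi`, `xi = beta * |B|`. Because the field is
quadrupolar around the line, the transverse magnetization component a
homogeneous receive coil picks up carries the geometric factor
`dz / sqrt(dx^2 + dz^2)`; the induced voltage is `s = -dM/dt`, evaluated by
central finite differences at `fs`. The model is exactly linear in the
concentration map, and noise (white Gaussian plus optional narrowband
interference lines, fully seeded) is added only after signal formation.

`beta` is a free calibration parameter, because the effective core moment of
the tracer (Perimag, 8.5 mg Fe/ml stock) is not published. The default
`beta = 1e4` 1/T makes a voxel leave saturation (`xi = 5`) when the FFL
approaches within 2 mm at 0.25 T/m, which reproduces the scanner's ~5 mm
resolution scale; the folded point response measured on the package's own
output has a full width at half maximum of roughly 4 mm along `z` and 7 mm
along `x` at the reduced test sampling rate. Néel/Brownian relaxation is
intentionally absent: it limits real tracers at high frequency but is not
part of the image-formation model implemented here, so simulated spectra are
a best case.

The nonlinear response concentrates signal energy at combination frequencies
`n*f3 + k*f1`. With the defaults, at least 95% of the noise-free energy of a
point source (after removal of the drive fundamentals) lies within
`|k| <= 20` of the harmonics — in practice about 95% already within
`|k| <= 5`. The sideband window half-width `k_max = 20` (1200 Hz, just under
half the harmonic spacing) was chosen from that measurement and is used both
for spectral bookkeeping and for the reconstruction band filter. Per-band
SNR is the band magnitude over the median magnitude of the 20 nearest
non-sideband bins; on pure noise this statistic sits slightly above 1
(Rayleigh mean/median is about 1.06). Peak picking keeps bands with
SNR >= 2 by default.

## From signal to image

The gradiometric receive coil of the hardware is emulated in software:
`filter_fundamental()` notches the exact FFT bins of `f1`, `f2`, `f3` and
DC, and `filter_harmonics()` keeps only the retained harmonic windows
(default `n` in 2..12, `|k| <= 20`). The default band selection drops the
first harmonic entirely: its window would border the strong drive region,
and the low-frequency content it carries is exactly what extended
structures aligned with the deflection axis collapse into (see artifacts
below).

`grid_raw()` co-registers the 1D filtered signal point-by-point at the known
FFL position, nearest-neighbor with per-pixel hit-count normalization. The
raw image is laid out as a 2x2 mosaic of FOV sub-images: positive/negative
FFL polarity in the top/bottom row blocks, forward/backward deflection sweep
in the left/right column blocks, with the backward block stored mirrored in
`x`. This constructive convention fixes the orientation bookkeeping that the
hardware description leaves open; `fold()` inverts it (un-mirror the
backward blocks, negate the opposite-polarity blocks, hit-count-weighted
average) and the round trip is tested explicitly. Folding four sub-images
with independent noise halves the noise standard deviation.

Reconstruction is image-based: `build_system_matrix()` simulates, for every
reconstruction pixel, the folded raw image of a unit point source through
the identical processing chain and stores it as a column of a dense linear
operator. Columns are kept signed and unscaled (up to one global factor)
rather than normalized per column: per-column normalization would break the
linear consistency `A c = fold(grid(signal(c)))` that the tests verify and
would spatially bias quantitation (e.g. stenosis grading). A fingerprint of
every build parameter travels with the matrix, and data reconstructed
against it must have been filtered with the same bands.

The inverse problem `min ||A c - b||^2 + lambda ||c||^2` is solved with a
deterministic regularized Kaczmarz iteration (row order fixed, dual-variable
formulation, non-negativity projection after each sweep; `lambda` is
specified relative to the largest squared row norm, default `1e-3`, 10
sweeps). Row-action solvers are the standard choice for real-time MPI
reconstruction; determinism was preferred over randomized sweep orders so
that every result in the package is bit-reproducible.

Multicontrast reconstruction reconstructs one acquisition twice with
different retained-band/regularization sets and returns both images plus
their clamped difference; concentrated markers keep relatively more weight
under a high-harmonic band set, extended tracer pools under a low-harmonic
one. The two parameter sets are the package's interpretation of "different
reconstruction parameters" — the hardware study does not enumerate them.

## Artifacts the twin reproduces

* **Orientation (pseudo-stenosis) artifact.** A homogeneous segment aligned
  with the deflection axis `x` modulates the deflection only at its ends, so
  its energy collapses toward low frequencies that the band filter discards;
  the same segment along `z` keeps full harmonic content. Reconstructed
  intensity is therefore lower for the x-aligned segment, which is how a
  perpendicular vessel branch can masquerade as a stenosis.
* **Edge artifacts and overscan.** Tracer just outside the FOV cannot be
  represented on a FOV-only reconstruction grid, so the solver explains its
  signal with spurious in-FOV structure. The reconstruction grid therefore
  extends `margin` (default 15%) beyond the FOV per side; the tests verify
  that the spurious in-FOV energy of an outside source shrinks when the
  margin is enabled.

## Phantoms

All generators are deterministic and conserve the requested iron exactly.

* `point_sample()`: a uniform disc (default 9 mm, an Eppendorf cap in
  projection) with a given iron amount; `dilution_to_mol()` converts a
  dilution of the 8.5 mg/ml stock (1:50 .. 1:800 gives 3.0 umol .. 0.19 umol
  with the 55.845 g/mol molar mass).
* `vessel_phantom()`: projected chord thickness of a tube (default 10 mm
  lumen) along a polyline, with a cosine-tapered stenosis over 30 mm whose
  grade scales the lumen diameter, an optional spherical aneurysm bulge, and
  an optional perpendicular branch. The perpendicular-integrated projection
  of a tube scales with lumen *area*, so `stenosis_grade_from_image()`
  estimates the diameter grade as `1 - sqrt(min/median)` of the along-path
  profile — using `1 - min/median` directly would report the area reduction
  (0.91 for a 70% diameter stenosis) instead of the diameter grade.
* `bolus_sequence()`: a tracer bolus (1 ml at stock concentration by
  default) advancing under a rectified-sinusoid pulsatile profile at 1 Hz
  scaled to a 50 cm/s peak; only the pump's peak velocity is documented for
  the hardware, so the 1 Hz rectified sinusoid is a declared choice. Iron is
  conserved until the bolus reaches the end of the path.
* `instrument_phantom()`: one point marker for a guidewire tip, two markers
  37 mm apart for the balloon catheter.
* `lettering_phantom()`: a deterministic bitmap-font test pattern scaled to
  about 60% of the FOV width.

The phantom grid defaults to 1 mm pixels over the 11 x 12 cm FOV; the
reconstruction grid defaults to 2 mm pixels (downsampled 2x for
conditioning).

## Safety and thermal calculators

The safety module recomputes, from first inputs, every operations number a
scanner operator needs: the magnetostimulation threshold
`B_pp = 47.5 mT * (1 + 1/(2 * 295us * f))` (79.96 ~ 80 mT pp at 2480 Hz,
above the 70 mT pp operating amplitude), SAR scaled as `f^2 B^2` from the
0.15 W/kg anchor at (2480 Hz, 35 mT), channel powers `R I^2 / 2`, copper
masses from the litz-wire geometry (pi mm^2 cross-section), per-burst
adiabatic heating `P dt / (m c)` (0.41 K and 0.18 K per 60 ms burst for the
two channels at the published powers), convective cooling
`alpha A dT / (m c)` and the resulting continuous-operation limit. Where the
hardware paper's own printed numbers are mutually inconsistent (its rounded
channel powers do not equal `R I^2 / 2` of its printed `R` and `I`; its
cooling range is printed without a per-second unit), the formulas are
authoritative and the calculators return the formula results.

`delta_T_limit` defaults to 50 K, the coil-to-air difference assumed in the
cooling estimate. The SAR calculator is an anchored scaling law, not a
tissue model.

## Problem sizes and tolerances

The full-scale configuration (496 kS/s, 124 x 128 raw images, 2 mm
reconstruction pixels) is practical but slow for a test suite, so the
package's tests and examples run a reduced configuration chosen once:
49.6 kS/s sampling (20 samples per deflection period), 62 x 64 raw images,
4 mm reconstruction pixels with 10% overscan, harmonics `n` in 2..8. At that
scale the deflection axis is sampled at roughly one sample per 11 mm of
sweep near the FOV center, so x-localization of a single reconstructed
column is reliable to one 4 mm pixel over most but not every position —
the point-recovery property is therefore stated, as in the full-scale
design, over a 5x5 source lattice with a >= 24/25 pass criterion.

Numerical details worth knowing: the Langevin function switches to its
series below `|xi| < 1e-5`; commensurability checks use a 1e-9 relative
tolerance; spectra refuse windows whose drive frequencies miss the FFT grid
by more than 1e-6 bins; gridding ties at pixel borders resolve by
`ceiling()`; the Kaczmarz residual is recorded per sweep and a
non-settling run is flagged rather than silently returned.

## What passing tests do and do not show

The synthetic experiments exercise the full software chain — encoding,
signal formation, spectral selection, gridding, folding, calibration-free
system-matrix inversion — under the scanner's nominal drive parameters, and
they reproduce the study-scale anchors (sideband arithmetic, dilution
masses, derated gradient, PNS/thermal numbers) exactly. They do not emulate
receive-chain electronics, relaxation-limited tracer physics, mechanical
vibration, or the unshielded-environment interference spectrum of a real
catheter laboratory; the noise model is white plus optional fixed lines.
Absolute signal units are arbitrary (per-mol moment `m_sat` is a scale
factor), so only relative amplitudes, positions and ratios are meaningful.
Real-hardware figures of merit — absolute detection limits, visualization
latency, X-ray hybrid behavior — are out of scope.
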