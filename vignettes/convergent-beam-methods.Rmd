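---
title: "Methods: simulating a convergent X-ray teletherapy beam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating a convergent X-ray teletherapy beam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cxbeam)
```

## The system being modelled

Conventional teletherapy delivers dose with *diverging* photon beams and
relies on overlapping fields to concentrate dose in the target.  A
convergent-beam device inverts this geometry: an electron beam is guided by
deflection magnets onto a bremsstrahlung target mounted off-axis, and the
collimated photon beam points *inward*, toward a focal spot.  Rotating the
assembly about the optical axis sweeps the source over a ring, so that over
a full turn the focal spot receives the superposed fluence of every
orientation while any single upstream voxel is only crossed by a fraction
of them.  `cxbeam` implements this chain end to end at desk scale: the
closed-form convergent depth-dose law, electron transport through voxelized
magnet maps, parametrised bremsstrahlung production and collimation, an
ASCII phase-space interchange format, turn and gantry-arc integration, and
collision-kerma dose deposition on voxel phantoms with clinical-style
metrics (DVH, isodose volumes, R50, focal-spot extension).

## The analytic depth-dose law

For a cone converging from entrance area $A(0)=\pi r_0^2$ to a focus at
depth $F$, the transversal area is $A(z) = A(0)\,(1-z/F)^2$.  The on-axis
primary dose is

$$D(z) \;=\; D_0\left(\frac{A(0)}{A(z)}\right)^{2}
  \sum_E w_E\, e^{-\mu(E)\,\rho\, z\sec\varphi},$$

with $\varphi = \arctan(h/L)$ the convergence half-angle of a source ring
of radius $h$ at axial standoff $L$, and $s(z) = z\sec\varphi$ the oblique
path length (the full path from the ring is $h\sec\varphi$ measured with
the complementary angle).  Two readings of this law deserve comment:

* **The square on the area ratio.**  Pure fluence conservation would give
  exponent 1; the law is implemented with exponent 2 exactly as published,
  and `on_axis_dose(..., area_exponent = 1)` switches to the
  fluence-conserving variant so the ambiguity is explicit rather than
  silently resolved.
* **The poly-energetic double integral.**  The spectral integral is
  discretised as an outer sum over spectrum bins with an inner path
  integral per bin — the only reading consistent with a depth-dependent
  attenuation exponent.

The implementation satisfies, by construction and by test, the
*conservation identity* $D(z)\,(A(z)/A(0))^2\,e^{+\mu\rho s(z)} = D_0$ to
$10^{-10}$, and the closed-form exponent agrees with an independent
numerical quadrature to $10^{-6}$.

### Spread-out peaks and the focal-spot parameter

Scanning the focal depth and superposing weighted peaks produces a photon
spread-out peak, the photon analogue of a spread-out Bragg peak.  The pure
area law diverges at $z=F$, so for superposition work the geometry carries
a focal-spot parameter $\delta$ (`focal_spot`, a fraction of $r_0$) that
regularises the area as $A_0\big((1-z/F)^2+\delta^2\big)$ — a finite waist
rather than a point focus.  The default is $\delta = 0$ (the printed law,
used by every exactness test); spread-out-peak synthesis uses $\delta
\approx 0.15$, giving peaks whose width is comparable to a 1 cm scan
spacing.  Peak weights come from non-negative least squares against a
constant on the plateau (`pracma::lsqnonneg`), which is deterministic.  As
with proton spread-out Bragg peaks, the flat region is quoted between the
proximal and distal scan depths minus half a scan spacing at each end: at
the exact outermost peak positions the superposition necessarily rolls
off, and the package's tests assert ripple $\le 3\%$ on that convention.

## Electron guidance

Primary electrons are sampled from Gaussian distributions in kinetic
energy (mean 6.0 MeV, FWHM 0.1 MeV by default, the reference filiform beam
being the zero-width limit), tilt, and transverse position
(FWHM $\to \sigma$ via $2\sqrt{2\ln 2}$).  Tracking through voxelized
magnetic-field maps uses a volume-preserving rotation stepper of the Boris
family: the direction is rotated about the local field by the exact
gyration angle and the position advances along the rotation chord.  Energy
is conserved identically (the field does no work on the stored energy at
all), and position accuracy is second order — halving the step reduces the
endpoint error against the analytic gyrocircle by at least a factor 4,
which the tests assert.  The default step (0.02 cm) stays below the
millimetric field voxels; field lookup is nearest-voxel (uniform field per
voxel) with an optional trilinear mode.  Synthetic dipole maps (plateau
plus cosine fringe, mirror-symmetric, $\ge 10\times$ plateau-to-edge
contrast) stand in for bench-measured maps, and `tune_dipole()` bisects
the plateau strength to a requested deflection — the software analogue of
trimming magnets when the beam energy changes.

**Idealised guidance in the pipeline.**  The full pipeline maps sampled
electrons onto the target with their spot and energy preserved and their
direction aligned with the bore axis, rather than tracking every electron
through the magnets.  The magnet stage is exercised and validated by its
own module; folding per-electron tracking into every multi-million-history
run would multiply the cost by orders of magnitude while, for a tuned,
well-centred system, changing the emission geometry only through
second-order aberrations.  What this idealisation drops — chromatic
dispersion of the hit position with electron energy, fringe-field
aberrations, canal-wall losses — is a known limitation, stated again
below.

## Photon production and collimation

The thick-target bremsstrahlung spectrum is the parametrised Kramers shape
$N(E) \propto (E_0-E)/E$ hardened by self-filtration through half the
target thickness ($e^{-\mu_W(E)\rho_W t/2}$; default 1.15 mm of tungsten),
truncated to $[0.05, E_0]$ MeV and sampled with within-bin jitter from 400
bins.  Characteristic K-lines are negligible at MV energies and off by
default.  The angular kernel is a forward-peaked Gaussian of
characteristic angle $m_ec^2/E_0$ about the bore axis.  A mean of 3
photons per electron is emitted into this modelled part of the spectrum —
the order of what a 6 MeV electron radiates above 50 keV in a thick
high-Z target.  Collimator acceptance is purely geometric: a ray survives
if it is inside the bore radius at both apertures (sufficient for a
cylinder, since the squared distance from the axis is convex along a
straight ray).  Survivors are scored on the plane $z = -21$ cm as
8-column records (type, energy, position, direction cosines; electron = 1,
photon = 2, positron = 3 — stated in the file header since conventions
differ between transport codes), and a full turn is the union of the
static phase space rotated to $n$ equally spaced angles (default 360).

## Device geometry defaults

The device frame adopts the one printed parameter set: ring radius
$h = 10$ cm, standoff $L = 30$ cm, focus at the origin, bore aimed at the
focus, a 0.2 cm target-to-bore gap, 100 mm collimator length, scoring at
$z=-21$ cm.  The electron spot default, $\sigma = 0.3$ cm, fills the
10 mm guidance canal (about $\pm1.7\sigma$ at the wall) — the device
description has the beam delivered through that canal, and a filiform spot
would make the focal footprint collapse to the bore-projection envelope,
which is not how a real accelerator spot behaves.  These choices were
fixed once, before any end-to-end dosimetry was measured, and are not
tuned per result.

## Dose deposition: primary-photon collision kerma

Each photon is ray-traced through the voxel grid with exact incremental
boundary crossing (validated against analytic chord lengths at
$10^{-10}$).  Per traversed voxel the surviving energy fluence interacts
with probability $1-e^{-\mu\rho\ell}$; the collision-kerma fraction
$\mu_{en}/\mu$ of the interacted energy is deposited, the remainder is
tallied as a *scatter surrogate*, and whatever crosses the far face is
tallied as escaped — so entering energy equals deposited + scatter
surrogate + escaped to better than $10^{-9}$ by construction.  For optical
depths below 0.05 the interaction probability uses a fourth-order series
(relative error $<10^{-8}$); the energy split stays exact either way.
Scattered-photon transport and secondary-electron transport are *not*
modelled: this is the standard kerma approximation driven by the
convergence/focusing geometry, which is what the headline results depend
on.  Statistical uncertainty uses the history-batch method (20 batches by
default).  Dose is reported in Gy per primary history; the per-history
normalisation counts each primary once per turn step and gantry
orientation, since the turn distributes a fixed current over angles.

Material data are coarse (~26-point, log-spaced) transcriptions of
standard mass attenuation and mass energy-absorption tables for water
(also standing in for soft tissue at $\rho=1$), compact bone, lung, air
and tungsten, interpolated log-log (exact at knots).  The water value at
1.25 MeV is stored as 0.0632 cm²/g to the precision used throughout the
analytic examples.

## Phantoms

All tests and examples run on synthetic phantoms: a water-equivalent cube
(default 10 cm at 2 mm voxels, centred on the focus), an ellipsoidal head
(bone shell, soft interior, spherical PTV, brainstem-like cylinder) and a
thorax (soft body, two $\rho=0.26$ lungs, bone spine, PTV inside a lung,
heart mask).  CT input is supported through `segment_ct()`: three-way HU
thresholding (defaults: air below $-800$, bone above $+200$ — declared
defaults, since no canonical thresholds exist) with an optional
specialist-style lung mask that takes total precedence, yielding the
four-region thorax segmentation.  Densities per label default to air
0.0012, lung 0.26, soft 1.0, bone 1.85 g/cm³.

## Dosimetry metrics

DVHs are cumulative voxel-counting curves; isodose volumes are level sets
of the maximum-normalised dose with 6-connected components; the R50
surface is the boundary voxel set of the half-maximum region; and the
focal-spot size metric is the *mean extension of the 95% isodose volume*:
the mean of the three orthogonal caliper extents of the largest connected
component, counting whole voxels (a one-voxel region has a one-voxel
extent, which is what makes the uniform-cube check exact).  An
equivalent-sphere-diameter alternative is available behind
`method = "equivalent_sphere"`.

## Convergence and uncertainty harness

`convergence_study()` reruns the full chain at several history counts and
reports the percentage deviation $\Delta D$ of the dose in a 1 cm sphere
at the focus against a high-count reference, plus the runtime fraction
$f_t$.  One reference run is shared across repeats — reference noise is
common mode, so repeating it would multiply cost without sharpening the
comparison — and each $(N, \text{repeat})$ run draws a deterministically
derived seed.  The package-scale study uses the 3 mm collimation (the
reference configuration of the fluence characterisation), 36 turn steps,
$N \in \{2\times10^3 \dots 2\times10^6\}$ against a $2\times10^7$
reference with 10 repeats: the $\Delta D$ medians fall monotonically and
scale as $1/\sqrt{N}$ between decades within a factor of two, reproducing
the structure of production-scale uncertainty tables one to two decades
down.  The production history count of $2\times10^9$ is accepted in
configuration; the package default is $2\times10^6$, a deliberate
desk-scale choice.

## Numerical and reproducibility choices

* Single master seed; every stage (beam chunk, emission chunk, study run)
  derives its own stream by hashing `(seed, stage, index)`, so chunked and
  repeated runs are bit-reproducible for a fixed configuration.
* Chunked streaming: the turn-integrated phase space is never fully
  materialised; rotation blocks are traced and accumulated in place.
* Ties and degenerate inputs: zero-density voxels deposit nothing and
  report zero dose; empty masks, empty spectra, out-of-span energies,
  non-increasing thresholds and infeasible plateaus raise typed errors
  naming the offending quantity.

## Known limitations

* **No scattered-photon or electron transport.**  Kerma underestimates
  penumbral blur and build-up; dose at interfaces is approximate.
* **Idealised magnet guidance in the pipeline** (see above).
* **Focal-spot extension is geometry-limited.**  With the adopted ring
  geometry the bore-to-focus magnification is about 2.6 and the focal
  region is elongated along the optical axis by roughly $1/\sin\varphi$.
  Both effects push the caliper extension of the 95% isodose volume above
  what a steeper, more compact converging assembly — or full transport on
  patient grids — would give: the desk-scale runs in
  `scripts/acceptance.R` report extensions moderately above the few-mm
  scale quoted for the clinical-grade simulation of the same collimators,
  while reproducing the strict growth with channel diameter.  The ring
  angle is the single most influential unpublished parameter; it is kept
  at the printed analytic-example value rather than adjusted to improve
  agreement.
* **The brems model is parametrised**, not a shower simulation: no
  electron-photon cascade in the target, no positrons (the particle-type
  code exists for interchange completeness), no neutrons.

## Problem sizes used in the shipped checks

End-to-end focal-spot runs use $5\times10^5$ primaries into a 10 cm water
cube at 2 mm voxels with 360 turn steps (about $10^6$–$6\times10^7$
transported rays depending on the collimator); the convergence study uses
the counts listed above.  These sizes were chosen as the smallest at which
the metrics are statistically stable at the voxel scale.
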