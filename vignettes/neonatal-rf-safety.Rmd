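---
title: "RF dosimetry and thermal safety modelling for neonatal ultra-high-field MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RF dosimetry and thermal safety modelling for neonatal ultra-high-field MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Imaging neonates in a 7 T adult head transmit coil raises a safety question
that adult dosimetry does not answer. A neonate is small enough that a head
coil exposes essentially the whole body; neonatal tissues carry more water
than adult tissues, which changes their dielectric properties; and a
neonate's immature thermoregulation and large surface-to-volume ratio mean
that, unlike an adult, it is not in thermal equilibrium with a 22 °C scanner
room — it must be insulated to avoid hypothermia, and insulation in turn
traps RF heat. `neodose` implements the analysis chain needed to reason
about these effects quantitatively: voxel phantoms, tissue property tables
with age adjustment, specific absorption rate (SAR) dosimetry with the
normalizations used in practice, a Pennes bioheat solver with a lumped
blood pool, and limit logic.

## What the package computes

**SAR.** Pointwise SAR is $\sigma |E|^2 / \rho$ with $|E|$ an RMS magnitude
(a deliberate, documented convention: no factor $\tfrac12$). Region
averages (head, whole body) are mass-weighted. The local-exposure quantity
psSAR10g is computed by growing a cube centred on each tissue voxel until
it encloses 10 g of tissue, fractionally weighting the outermost shell so
the enclosed mass is exactly 10 g (an IEC 62704-1-style simplification).
Cubes may only use grid-interior content; voxels whose cube would have to
cross the grid boundary are marked invalid and excluded from the peak.
Correctness is established against an independent exhaustive search
(integral-image box sums over every centre and fractional cube size) rather
than against any particular commercial implementation, whose internals are
not public.

**Normalizations.** SAR summaries are reported per input power (W/kg/W),
per net forward power (forward − reflected), per absorbed power, and per
mean squared transmit field $\overline{|B_1^+|}^2$ in a central axial
slice. The slice mean is taken over tissue voxels only, because $B_1^+$ in
air carries no exposure meaning. Per-$B_1^{+2}$ values are invariant to
drive power, which the tests assert. In the position-shift experiment the
normalization slice translates with the model, emulating imaging of the
same anatomy at a shifted position.

**Bioheat.** The solver integrates the Pennes equation
$\rho c\, \partial T/\partial t = \nabla\!\cdot\!(k \nabla T) + \rho\,\mathrm{SAR}
+ \rho\, q_{met} + W_b c_b (T_{blood} - T)$
with explicit forward Euler on the voxel grid. Face conductances use the
harmonic mean of adjacent conductivities; tissue faces adjacent to in-grid
air receive a Robin flux $h (T - T_{ambient})$; domain-boundary faces are
adiabatic (phantoms keep an air margin, so the entire exterior surface is
convectively coupled). The perfusion coefficient converts from the
interface unit (mL blood · min⁻¹ · kg tissue⁻¹) as
$W_b = \rho_{tissue}\, w\, \rho_{blood} \cdot 10^{-6}/60$ (kg · m⁻³ · s⁻¹).
The automatic time step is the positivity bound — the minimum over solid
voxels of $\rho c$ divided by the total per-volume conductance (faces plus
perfusion) — times a 0.9 safety factor; at 2 mm resolution this is a few
seconds, and an hour of simulated time takes a couple of minutes of wall
time on one core. Explicit stepping was chosen over implicit methods
because every term is then verifiable against closed forms to machine
precision, which the validation suite exploits.

**Blood pool.** With the variable-core option the blood temperature is a
lumped state integrating the net tissue–blood exchange over a finite blood
volume (324 mL, typical of a ~3.5 kg term neonate), with the same time
step (operator-split, exchange evaluated at the current temperatures).
Runs always start from the equilibration protocol — uniform 37 °C, ambient
22 °C, h = 8 W m⁻² K⁻¹, fixed blood temperature, 60 minutes — because
activating the blood pool from the unphysical uniform state produces
unreliable trajectories.

**Compliance.** Limits default to head-average SAR 3.2 W/kg, psSAR10g
10 W/kg, whole-body 4 W/kg, core rise 0.5 °C and absolute 39 °C. The
allowed drive power is the minimum over SAR limits of limit divided by the
per-watt summary; thermal crossings are found by linear interpolation
between samples. The core-rise baseline is the core temperature at RF
onset (end of equilibration). Since a passively cooling neonate may start
below 37 °C, a rise measured from 37 °C can differ; both are computable
from the emitted series, and the onset-referenced value is the default.

## The synthetic phantom and what it does (not) represent

The published voxel models are MRI- and CT-derived and cannot be
reconstructed from printed text, so the package ships a parametric
stand-in: nested ellipsoids forming a layered head
(skin/fat/skull/CSF/brain, head region ≈ 1030 mL), a layered torso with
heart (wall plus chamber blood), lungs, liver and bony spine, flexed
limbs, eyes, a cartilaginous nose and an optional hand near the face — 13
tissue classes at 2 mm resolution, mass-calibrated to 3.50 kg (within 2 %)
by scaling torso/limb cross-sections. A fixed seed fixes the phantom
bit-exactly; a 2 % geometric jitter models inter-subject variability.
An insulating wool shell (k = 0.04 W m⁻¹ K⁻¹, zero perfusion and
metabolism, default 10 mm) can be wrapped around the body, leaving a face
aperture uncovered.

The phantom reproduces bookkeeping (masses, volumes, masks, tissue
classes) and supports property-based validation; it does **not** reproduce
anatomical SAR or temperature maps. Tests passing on this phantom
demonstrate the correctness of the algorithms and the qualitative
structure of the thermal results, not subject-specific predictions.

Two calibration choices were made once and documented here:

* **Surrogate field structure.** Full-wave electromagnetics is out of
  scope, so exposure fields are parametric: a radial-gradient mode, a
  uniform mode, and a superficial-hotspot mode whose default places a
  Gaussian hotspot on the posterior neck surface — where head-coil local
  SAR maxima occur — with an axial envelope representing the finite
  sensitive length of a head coil. The hotspot amplitude (0.8 over a unit
  baseline) was set so the ratio of the 10 g peak to the head-average SAR
  falls in the published 2.3–3.1 range; with it, the head-average limit
  binds just ahead of the 10 g limit, as reported for real models. The
  |E| grid is scaled so the absorbed power equals forward − reflected −
  radiated exactly; budgets therefore close by construction, and imported
  budgets are validated to 1 %.
* **Neonatal metabolic scaling.** The property table carries adult
  per-tissue values (the conservative convention for dielectrics and
  thermal conductivity/heat capacity). For heat *production*, adult rates
  applied to neonatal proportions misbehave: the phantom's brain is ~15 %
  of body mass, and the adult grey-matter rate (15.5 W/kg) alone yields
  ~11.5 W total — over 3 W/kg of body mass, where term neonates produce
  roughly 2 W/kg. Neonatal thermal runs therefore scale metabolic rates by
  0.5 (≈ 1.6 W/kg body), after which the insulated phantom drifts
  about −1 °C/h without RF and the uninsulated one several times faster —
  the qualitative behaviour reported for passively cooling neonates.

## Age-adjusted dielectric properties

Adult permittivities and conductivities are scaled tissue-by-tissue by
newborn/adult ratios. Authoritative ratios are not publicly tabulated for
humans; the packaged `scaling_neonate.csv` is a clearly labelled synthetic
default following the water-content argument (ratios ≥ 1, larger for
low-water tissues such as fat and bone, near unity for CSF and blood) and
should be replaced through the same CSV interface for publication-grade
work. Scaling touches dielectrics only; thermal properties and density
stay at adult values (density because model weight bookkeeping uses
database densities; thermal properties because higher water content would
increase conductivity and heat capacity, making adult values
conservative). Property lookup refuses frequencies more than 10 % from a
stored entry instead of interpolating across dispersion.

## Numerical choices and edge cases

* Voxel indices are 1-based with world coordinate (index − 0.5) × voxel
  size; axis order x = left-right, y = posterior-anterior,
  z = inferior-superior.
* Shifts are quantized to whole voxels; the sub-voxel residual is recorded
  in the model metadata. Voxels shifted off the grid are dropped with a
  warning; the shift experiment flags rows losing > 20 % of tissue.
* Ties in the 10 g peak break to the lowest linear (column-major) index.
* Core mask = heart ∪ chamber-blood ∪ brain, each eroded by one voxel
  (6-neighbourhood); a compartment that erosion would empty (e.g. a
  single-voxel heart in a toy grid) falls back to its un-eroded voxels.
  Core temperature is the mass-weighted mean over this mask.
* A single h covers the whole exterior (skin and blanket alike); the
  blanket insulates via its low conductivity, not via a different h.
* The temperature-dependent perfusion ramp (factor 1 below 39 °C, linear
  to a per-tissue maximum at 45 °C) exists for adult-mode runs only;
  neonatal runs use temperature-independent perfusion, which is
  conservative. The ramp maxima are configurable defaults, as published
  parameterizations vary.
* The solver aborts with a diagnostic if temperatures leave (−150, 150) °C
  or become non-finite.

## Problem sizes used in the validation suite

The analytic and conservation checks run on deliberately small grids
(single voxels to 64³) where closed forms are exact or reachable; the
protocol demonstration runs the full synthetic neonate (96 × 96 × 136 at
2 mm) through equilibration, one hour of exposure at the allowed power,
and an h sensitivity comparison. These sizes were chosen so the whole
suite completes in minutes on a single core while still exercising every
code path at the study's native 2 mm resolution.

## Known limitations

* Exposure fields are surrogates; no coil, shield or bore
  electromagnetics, no S-parameters, no B1 homogeneity prediction.
* Evaporative and radiative losses are not separate mechanisms; they are
  folded into the single h, which is itself uncertain — hence the built-in
  ±10/±20 % h sweeps.
* No active thermoregulation, incubator or radiant-warmer models.
* One frequency context at a time; no Cole–Cole dispersion modelling.
* The synthetic phantom's surface area (~0.18 m²) is somewhat below a real
  neonate's (~0.22 m²), one reason its passive cooling rates differ in
  magnitude from published in-vivo figures while preserving their
  ordering.
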