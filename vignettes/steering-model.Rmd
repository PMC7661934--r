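---
title: "Modelling radial current steering and battery current draw in directional DBS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling radial current steering and battery current draw in directional DBS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vtasteer)
```

## The question

Directional deep brain stimulation (DBS) leads replace a cylindrical
contact with three 120°-spaced segments, so the stimulation field can be
steered radially by splitting the cathodic pulse amplitude between two
adjacent segments (a *fractionalization*, e.g. −70 %/−30 %). Two
commercial paradigms implement such a split very differently:

* **MICC** (multiple independent current control) drives both segments
  *simultaneously* from independent current sources. The extracellular
  fields add before the tissue responds.
* **Interleaving/MSS** alternates two single-electrode pulse trains.
  Each field acts on the tissue alone; the effective stimulated volume
  is the *union* of the two single-electrode volumes, and their
  *intersection* sees twice the pulse rate.

`vtasteer` builds volumes of tissue activated (VTAs) for both paradigms
under matched conditions, measures how accurately each steers the VTA to
the angle the linear proportion of the split predicts, and attaches an
implantable pulse generator (IPG) battery current-draw model so the
energy cost of the two paradigms can be compared at matched VTA size.

## Field and activation model

The lead is an eight-contact 1-3-3-1 geometry (ring, 3+3 segments,
ring). Contacts are discretized into weighted surface point sources and
the extracellular potential is the analytic point-source superposition
in an infinite homogeneous medium,

$$V(\mathbf{x}) = \sum_k \frac{I_k}{4\pi\sigma\,|\mathbf{x}-\mathbf{x}_k|},$$

with bulk conductivity $\sigma = 0.2$ S/m and cathodic (negative)
currents. No finite-element solve is performed: the homogeneous-medium
potential is exact for this idealization, fully deterministic, and
linear in the amplitudes — linearity is what makes MICC field summation
and amplitude titration exact operations rather than numerical ones. A
500 µm, 0.1 S/m encapsulation layer is carried as metadata: a resistive
shell concentric with the sources changes the potential only inside the
shell, so it is represented by excluding the encapsulated tissue from
the axon lattice rather than by a field correction. Each VTA records
this idealization in its provenance.

Neural activation uses the classic *activating function* surrogate on a
lattice of straight 5.7 µm myelinated axons oriented perpendicular to
the lead: planes containing the lead axis every 30°, a 0.5 mm grid of
(radius × height) positions per plane, 21 nodes per axon at 0.5 mm
spacing (approximately the internodal length of a 5.7 µm fibre). An axon
is activated when the peak discrete second difference of the potential
along its nodes, $\max_i (V_{i-1} - 2V_i + V_{i+1})$, reaches a
threshold. The full multi-compartment cable model it replaces is outside
the scope of this package; the surrogate preserves the mechanism under
study — MICC thresholds the *summed* field, Interleaving/MSS thresholds
each field *alone* — while staying linear and desk-scale.

The surrogate has a single free scalar, the threshold. It is calibrated
once against a published single-electrode anchor (1.6 mA → 3.00 mm
radius): the threshold is placed at the activating-function value of the
boundary axon, so the anchor amplitude is also the smallest amplitude
reaching the anchor radius. `anchor_amplitudes()` carries the full
published amplitude–radius series for the ring-mode and single-electrode
settings; the calibrated model maps the single-electrode series onto a
non-decreasing radius sequence, which `analysis/01_calibrate_model.R`
verifies.

### Geometry choices that the tests rely on

* **Lattice alignment.** Radial lattice positions start at the first
  multiple of half the lattice spacing at or beyond the inner margin
  (shaft 0.65 mm + encapsulation 0.5 mm → first axon ring at 1.25 mm).
  Rasterized VTA boundaries then fall on the 0.25 mm grid of the target
  radii, so anchors like 3.00 mm are exactly attainable.
* **Rasterization.** Each activated lattice point fills the voxels
  (0.1 mm) within half the lattice spacing of it, measured along its
  plane's radial/tangential/vertical axes — an oriented square prism.
  Axis-aligned cubes are not invariant under the 60°/120° reflections
  that map the lattice onto itself and were found to bias the rotation
  metric by several degrees; the oriented footprint makes the continuous
  union covariant with the lattice symmetry while still tiling space
  solidly (volumes have no internal gaps).
* **Cross-sections.** Steering metrics live on a polar raster (1° ×
  0.05 mm) at the vertical centre of the activated electrodes, sampled
  at cell centres. For lattice-built VTAs the occupancy is evaluated
  against the continuous point footprints rather than the voxelized
  volume: per-point polar coverage depends only on the point radius, the
  sample radius and the relative angle, so mirror-symmetric settings
  produce *exactly* mirrored occupancy. This is what makes the −50/−50 %
  deviation exactly 0° rather than "0° up to voxel noise". Synthetic
  voxel volumes (as used in the metric unit tests) fall back to
  voxel-membership sampling.

## Steering metrics

The *rotation angle* of a VTA is the direction of the line through the
lead axis that splits the cross-section into two equal areas, found by a
1° sweep (ties toward the smaller angle; of the line's two directions,
the one nearer the occupancy centroid is reported). The *radius* is the
outermost occupied sample along a direction; the *deviation* is the
circular difference from the linear-proportion expectation (fraction on
the secondary electrode × 120°). Volumes sum voxel volumes; overlap
percentages are voxel set ratios.

## Titration

For every fractionalization and target radius (2.00–4.00 mm in 0.25 mm
steps) the total amplitude is adjusted by bisection until the VTA
reaches the target radius. The controlled radius is the overall maximum
cross-section radius (`control = "max"`). The equal-area-bisector radius
is available as `control = "bisector"`, but it is not the default: the
bisector direction swings as the VTA rotates, so the radius along it is
not monotone in amplitude, which can make bisection settle on
non-minimal amplitudes and even invert the amplitude ordering between
paradigms. The maximum radius is exactly monotone because the activating
function is linear in amplitude, so the activated set only grows.

Bisection stops when the achieved radius is within half a radial step
(0.025 mm) of the target or when the amplitude interval is below
0.01 mA, whichever comes first. Because the surrogate's radius is a step
function (0.5 mm lattice), only targets aligned with the lattice
quantization (here the whole and half millimetres) converge in radius;
off-grid targets converge on the amplitude interval and report the
achieved radius with `converged = FALSE`. For Interleaving/MSS the ratio
splits the amplitude across the two alternating programs and the
controlled radius is that of the union VTA; when the weaker program's
field nowhere reaches threshold, VTA 2 is reported absent — the
mechanism behind Interleaving steering failures at strongly unequal
splits.

## Energy model

Battery current draw (µA) at pulse width 60 µs, frequency 130 Hz,
battery 2.8 V and overhead 4.9 µA per program:

* MICC: $I = I_{oh} + \sum_i I_{E_i}\,PW\,f\,V_{max}/V_{bat}$ with
  $V_{max} = \max_i I_{E_i} Z_{E_i}$ (all sources share one compliance
  rail).
* Interleaving/MSS: $I = N I_{oh} + \sum_i I_{E_i}\,PW\,f\,V_{E_i}/V_{bat}$
  with $V_{E_i} = I_{E_i} Z_{E_i}$ (each program pays its own overhead
  but sees only its own load).
* Coactivation (single source, parallel contacts):
  $I = I_{oh} + I_{tot}\,PW\,f\,V_{eq}/V_{bat}$ with
  $V_{eq} = I_{tot} / \sum_i Z_{E_i}^{-1}$.

Amplitudes are in mA and impedances in kΩ (their product is volts);
values are rounded to 0.1 µA only for reporting. At a single electrode
all three formulas coincide. At equal impedances $V_{eq} \le V_{max}$,
so coactivation never draws more than MICC. Note that the three
expressions are evaluated at each paradigm's *own* titrated amplitude:
the study design compares settings producing VTAs of matched radius.
(At artificially matched amplitudes the comparison can flip at high
amplitude, where the $V_{max}$ rail term outgrows the doubled overhead.)

## Synthetic impedance dataset

The clinical current-draw scenario needs a structured set of
directional-electrode impedances: 12 subjects × 2 leads × 2 directional
levels × 3 electrodes × 7 visits. The real clinical collection is not
redistributable, so `generate_impedance_dataset()` produces a synthetic
stand-in: impedances from a truncated normal (mean 2.99 kΩ, the
published clinical mean; sd 0.60 kΩ, a plausible clinical spread — not
published; truncation at 0.3 kΩ) with AR(1) visit-to-visit correlation
0.8 per electrode, modelling slow impedance drift. The missingness
structure — 326 complete three-electrode (lead, level, visit) groups
plus exactly one two-electrode group, 980 records — is the unique
composition simultaneously consistent with the published totals (980
measurements, 1958 ordered pairs, 978 ring-mode permutations); it is
inferred, flagged as such, and configurable. What the generator does
*not* emulate: real impedance distributions are likely skewed and
device-censored, inter-electrode correlations within a level are
ignored, and no systematic post-implant impedance drift is modelled —
so passing tests validate the pipeline's arithmetic and counting on
realistic structure, not clinical impedance physics. (The source report
describes the clinical impedances as normally distributed citing a KS
test with p < 0.001, which would conventionally *reject* normality; the
generator treats normality as its assumption and this package's
KS/Lilliefors wrapper reports the test as usual.)

## Statistics

Summaries are median (25–75 % IQR) with quartiles by linear
interpolation of order statistics (`quantile` type 7; the source's
method is unstated). Paired comparisons across the small per-cell grids
use the Wilcoxon signed-rank test (zero differences dropped; exact null
for n ≤ 25, normal approximation beyond), one-sided in the directions
the study design predicts: MICC larger volumes, lower deviations, lower
amplitudes and currents; coactivation below MICC. The clinical-scenario
permutation samples are large, so those comparisons use paired t-tests.
Normality screening uses the Lilliefors variant of the KS test
(estimated mean/sd). No multiple-testing correction is applied, since
p-values are reported per comparison.

## Problem sizes and determinism

The default lattice (12 planes × 10 radii × 19 heights, 21 nodes per
axon) and the 0.1 mm voxel grid build a VTA in well under a second, so
the full 9-radii × 5-fractionalization grid (plus ring-mode and
single-electrode references) completes in under a minute; the test suite
exercises a 3-radii (2.00/3.00/4.00 mm) version of the same grid, which
spans the study range while keeping the suite quick. Everything in the
steering pipeline is deterministic — the only randomness in the package
is the impedance generator, which is seeded and restores the caller's
RNG state.

## Known limitations

* The activating-function surrogate is linear: any positive amplitude
  activates axons close enough to the contact. Its no-VTA floor (the
  innermost lattice ring's threshold) is therefore lower than a
  nonlinear cable model's, and Interleaving VTA-2 failures appear only
  at the smallest radii and most unequal splits rather than across the
  whole radius range.
* Homogeneous isotropic tissue only; no anisotropy, no heterogeneity,
  no capacitive effects, and electrode impedance does not shape the
  field (it enters only the energy model).
* Steering is characterized on one cross-section plane at the centre of
  one directional level; vertical steering and multi-level settings are
  out of scope.
* Absolute VTA volumes are surrogate-dependent and smaller than
  cable-model volumes; comparisons between paradigms on the same grid
  (ratios, orderings, overlaps) are the intended use.
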