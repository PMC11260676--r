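---
title: "4D dose reconstruction for scanned proton beams: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{4D dose reconstruction for scanned proton beams: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(proton4d)
```

## The problem

Pencil-beam-scanning (PBS) proton therapy delivers a plan spot by spot:
fields are split into energy layers (one Bragg-peak depth each), and each
layer is a raster of weighted beamlets. When the anatomy moves while the
spots are being painted — breathing with a period of a few seconds, the
heartbeat at roughly 0.8 s — two distinct dosimetric effects appear:

* **dose blurring**: the time-averaged anatomy smears the dose edge, an
  effect that would occur even if the whole plan were delivered in every
  phase;
* **the interplay effect**: the interference between the spot delivery
  timeline and the motion trajectory, which produces hot and cold spots
  inside the target that blurring alone cannot explain.

`proton4d` implements the standard 4D reconstruction that separates the
two. A plan is simulated on a synthetic 4D phantom; three doses are
reconstructed and compared:

* the **3D static dose** — the plan dose on the average-intensity
  projection (AIP) of the phases, ignoring motion;
* the **4D accumulated dose** — the full plan recomputed on every phase,
  warped to the reference phase through the phase displacement fields, and
  averaged with equal weights 1/10 (spots uniformly distributed over the
  cycle): blurring only;
* the **4D dynamic dose** — the plan split into 10 per-phase sub-plans
  from an explicit beam-time model, each sub-plan's dose warped from its
  phase to the reference and summed: blurring plus interplay.

The single-fraction 25 Gy(RBE) prescription, the 95% ITV coverage
normalization, the 10-phase binning, the RBE factor 1.1, and the
dose-blurring/interplay comparison design mirror the cardiac-SBRT use case
(arrhythmia substrate ablation), where both respiratory and cardiac motion
matter.

## The synthetic 4D phantom

No public 4DCT/4DcCT data accompany this problem, so the package's
generator is a first-class module rather than a test fixture. It emulates:

* a homogeneous water body (sphere, radius 55 mm) on a 2-mm isotropic
  grid, 57^3 voxels;
* a spherical target (CTV analogue, radius 10 mm) and adjacent spherical
  OARs;
* ten motion phases (0%–90%) with analytic periodic motion and the exact
  displacement field from the reference (0%) phase to every phase;
* the AIP as the voxelwise mean of the phase densities.

Two motion modes are provided. **Respiratory** motion is a time-dependent
translation with default peak amplitude (0, 2, 8) mm LR/AP/SI and period
4 s; **cardiac** motion is a radial contraction/expansion about a cardiac
centre — an affine scaling whose displacement is 2.5 mm at the 25-mm
reference radius — with period 0.8 s (75 bpm). Both use the temporal
waveform `(1 - cos 2*pi*phi)/2`, which is zero at the 0% phase, so phase 0
is exactly the reference geometry. The published study does not report its
patients' motion amplitudes; these defaults are representative clinical
magnitudes (SI-dominant breathing of several mm; cardiac wall excursions
of a few mm) chosen once, not fitted.

Two design choices keep the phantom analytically exact:

* **Motion core.** The displacement is spatially constant (respiratory) or
  exactly affine (cardiac) inside a core sphere around the structures and
  cosine-tapers to zero towards the body edge. Structures are validated to
  lie inside the core, so the per-phase structure masks can be rasterized
  from the analytically transformed primitives — translation or scaling of
  a sphere — with **no interpolation on the mask path**. The interpolating
  alternative, `warp_mask()`, is retained to quantify interpolation loss.
* **Voxel-centred geometry.** Default grids have odd voxel counts so the
  phantom centre is a voxel centre; rasterized sphere volumes are then
  within ~2% of the analytic volume and stable to sub-voxel motion shifts
  (the conservation guarantee is stated for radii of at least 5 voxels).

Motion-envelope contouring follows the clinical recipe: the ITV is the
union of the 10 per-phase target masks on the reference frame, each OAR
gets an IRV union, and an `OAR_real` surrogate for the "contoured on the
AIP" structure is rasterized at the time-averaged displaced position (the
mean of the cosine waveform over the 10 phase fractions is exactly 0.5).
How a human contourer on an AIP image relates to the time-averaged anatomy
is not quantifiable here; the mean-displacement stand-in is an assumption
and is documented as such.

Heterogeneity (a low-density insert) is available but off by default: with
a homogeneous phantom the per-phase plan doses are identical in room
coordinates, which makes the 4D machinery cheap and its invariants exact.
In heterogeneous mode the per-phase density is the reference density
pulled back through the phase field with the small-displacement inverse
approximation `rho_k(x) = rho_ref(x - u(x))`.

## The analytic dose engine

The commercial Monte Carlo engine of a TPS is out of scope; the package
uses an analytic pencil-beam model designed for a sharp, range-accurate
Bragg peak rather than absolute dosimetric fidelity:

* **Range–energy**: `R[mm] = 10 * 0.0022 * E^1.77` (standard power-law fit
  for protons in water), invertible in closed form; deliverable energies
  70–230 MeV.
* **Lateral spot size**: linear interpolation between the machine anchors
  sigma(70 MeV) = 7.2 mm and sigma(230 MeV) = 2.6 mm, broadened with depth
  as `sigma(d)^2 = sigma_air^2 + (0.02 d)^2` (a small multiple-Coulomb-
  scattering-like term).
* **Depth dose**: a rising entrance plateau plus a Gaussian peak whose
  maximum sits *exactly* at the model range (the plateau is constant-level
  continued with the peak Gaussian beyond the range, so the analytic
  argmax is the range itself); the curve is cut to zero beyond
  `range + 3 * peak sigma`. The peak width is the range-straggling law
  `0.012 R^0.935` floored at 2 mm so the default 2-mm grid resolves it.
* **WEPL**: per-field water-equivalent depth is computed by resampling the
  density on a beam-aligned lattice (1-mm steps), cumulative integration
  along the beam axis, and trilinear sampling back at voxel centres; a
  per-point `radiological_depth()` trapezoidal integrator provides the
  reference implementation.
* **Spot dose**: `mu * IDD(WEPL) * Gaussian2D(BEV offset) * RBE *
  calibration`, truncated at 3.5 lateral sigma. The absolute calibration
  (400 Gy mm^2/MU) is arbitrary — the study machine publishes none — and
  is chosen so the default plan's normalization factor lands near 1,
  keeping optimizer weights far from the MU clip bounds.

Fields are parallel coplanar beams in the axial plane (divergence ignored
at phantom scale). Dose grids are 2-mm isotropic by default, matching the
clinical dose-grid setting.

## Planning

`make_plan()` places energy layers distal-first so their ranges tile the
target's WEPL interval (5-mm steps by default; layer and spot spacing are
config parameters, not published machine data). The proximal layer is
clamped at the machine's shallowest deliverable range, R(70 MeV) ≈ 41 mm:
no range shifter is modelled, so a target edge a few millimetres shallower
is covered by that layer's peak width instead. Spots go
on a 5-mm rectangular raster covering each layer's beam's-eye-view slab
projection with a 5-mm margin, ordered serpentine — the delivery order the
time model consumes. Weights start at 1 MU and are optimized by a
deterministic multiplicative correction (influence-weighted mean of
prescription/dose per spot), clipped to the machine bounds [0.02, 4] MU
each iteration. Plan normalization is then applied as a dose-level scalar
stored on the plan — mirroring TPS practice — so the MU-bound invariant
refers to the optimizer output and D95(ITV) equals the prescription
exactly. Three fields at 0/120/240 degrees are the default ("three or four
coplanar fields" is the clinical arrangement). Rescanning and robust
optimization are deliberately absent: the point is to expose motion
effects, not to mitigate them.

## Delivery timing and sub-plans

The beam-time model advances one continuous clock through the plan in
delivery order: drilling `mu / mu_rate`, spot-to-spot travel
`distance / scan_speed`, `layer_switch_s` between layers,
`interfield_gap_s` between fields. Defaults (100 MU/s, 10 m/s, 1 s, 5 s)
are representative cyclotron constants and are config-exposed; the study
adopts an accelerator time-structure model whose constants it does not
print. Delivery commences at the 0% phase (t = 0); a per-field phase-reset
variant is available behind a flag because the literature wording is
ambiguous on whether each field restarts the cycle.

Each spot is assigned the phase of its **drilling-interval midpoint** —
whole spots, never split MU; the midpoint choice minimizes boundary bias
and is the documented convention (start- or end-time assignment is a
one-line change). Constant periods (4 s, 0.8 s) are assumed; irregular
traces are future work, as in the source study.

## Metrics and statistics

DVH metrics use the continuous (interpolated) convention: `Dx` is the
minimum dose to the hottest x% with linear interpolation between sorted
voxel doses, and the structure `Vx` is its exact piecewise-linear inverse
— so after normalization V25(ITV) = 95% follows identically from
D95(ITV) = 25 Gy. Near-duplicate dose values (floating-point twins from
symmetric spot placement) are merged at a relative 1e-9 before
interpolation. Whole-grid isodose volumes (the denominators of the
conformity and gradient indices) use plain voxel counting, which is what
their worked definitions imply. Dmax/Dmin are voxel extremes, not
0.03-cc clinical maxima. The indices are the Paddick conformity index
`CI = V_T,rx^2 / (V_T V_rx)`, the homogeneity index
`HI = (D2 - D98)/Dmean`, and the gradient indices
`GI = V50%/V100%`, `GI_high = V75%/V100%`, `GI_low = V25%/V100%`.

Paired comparisons (3D static vs 4D dynamic; 4D accumulated vs 4D dynamic
for the interplay isolate) use the Wilcoxon signed-rank test with zero
differences dropped and mid-ranks for ties, exact two-sided p by full
2^n enumeration for n <= 12 and a tie-corrected normal approximation with
continuity correction above; flags are `*` for p < 0.05 and `**` for
p < 0.01 (strict). No multiple-testing correction is applied, matching
per-metric clinical reporting. The enumeration is implemented in-package
because the exact-with-ties case is needed; base R's `wilcox.test` serves
as an independent cross-check in the tests.

## Orchestration

The pipeline is function-driven: `run_subject()` chains phantom,
contouring, planning, timing, and reconstruction for one synthetic
subject and mode; `run_cohort()` repeats it over seed-jittered subjects
(default 12, the size of a typical small clinical cohort) and emits the
comparison tables; `run_pipeline()` writes the file artifacts (NIfTI
volumes, plan JSON, timeline CSV, metric CSVs, manifest). NIfTI is the
implemented volume interchange format (via `RNifti`). There is no shell
entry point: users of an analysis package like this drive it from R, and
`scripts/acceptance.R` shows the canonical scripted run.

## Problem sizes and expectations

The default phantom (57^3 at 2 mm, ~650-spot plans) runs a full
static + accumulated + dynamic reconstruction in tens of seconds; the test
suite's directional cohort uses 5 seeds per mode. What passing tests show:
the machinery is exact where exactness is claimed (partitions,
normalization, zero-motion degeneracy, closed-form indices) and reproduces
the *direction* of the clinical findings — dynamic doses degrade CI,
HI, and GI relative to static, and slow large-amplitude respiratory motion
perturbs target coverage far more than fast small-amplitude cardiac
pulsation (more phases are sampled per energy layer at 0.8 s, averaging
interplay out). What they do not show: agreement with any patient's
numbers — real 4DCT anatomy, deformable registration error, Monte Carlo
dose, and machine log files are all outside the model.

## Known limitations

* Homogeneous water by default; the heterogeneous path uses an
  approximate density pull-back and a simplified WEPL model.
* Dose warping is trilinear pull-back without energy/mass correction;
  out-of-grid samples contribute zero dose (phantom motion is interior by
  construction).
* Static and 4D doses live on different frames (AIP vs reference phase);
  comparisons are DVH-scalar-level only, never voxelwise across frames.
* The equal 1/10 phase weighting of the accumulated dose follows the
  "averaged over phases" convention; duty-cycle weighting is not
  considered.
* No setup/range/biological uncertainty, no DICOM interchange, no
  beam-angle optimization.
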