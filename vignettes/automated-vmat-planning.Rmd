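---
title: "Automated single-arc VMAT planning: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated single-arc VMAT planning: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What this package models

`arcplan` is a desk-scale re-creation of a scripted, fully automated
volumetric modulated arc therapy (VMAT) planning workflow for locally
advanced rectal cancer, together with the evaluation apparatus used to
judge such plans. A clinical implementation of this workflow lives inside
a commercial treatment planning system and drives its proprietary
optimizer and collapsed-cone dose engine; here every component is
re-implemented in simplified, fully transparent form so that the
*workflow logic* — automatic structure derivation, goal-driven objective
construction, staged optimization with hotspot correction and coverage
escalation, plan evaluation, QA — can be exercised, tested and studied
end to end without patient data or vendor software.

The package therefore contains three layers:

1. a **synthetic pelvic phantom** generator standing in for planning CT +
   contours,
2. a **linear pencil-beam arc dose engine** and a two-stage (fluence,
   then aperture) optimizer standing in for the TPS optimizer, and
3. the **plan evaluation toolbox**: DVH metrics, conformity/homogeneity
   indices, clinical-goal reports, plan sums, gamma analysis, modulation
   complexity, and the exact Wilcoxon signed-rank test for paired cohort
   comparisons.

## The synthetic phantom

The phantom emulates the anatomy the planner assumes: an elliptical
water-equivalent body (relative electron density 1.0 on air 0.0); a gross
rectal tumour on the posterior midline; a large concave nodal/mesorectal
target that wraps posteriorly around the anterior organ compartment (the
classic "horseshoe"); a bladder abutting or slightly overlapping the
target anteriorly; anterior–superior small bowel; and two lateral
femoral heads. Organs are parameterized superellipsoids with a small
seeded jitter on centres and semi-axes; identical `phantom_spec()` values
give bit-identical phantoms.

Targets are not drawn directly: the clinical target volume (CTV) is grown
from the tumour with the protocol margins (5 mm anterior–posterior and
right–left, 20 mm craniocaudal), united with the nodal compartment
(nodes unexpanded), and the planning target volume (PTV) adds a 5 mm
isotropic setup margin, clipped to the body — the same margin operations
exposed to users via `build_targets()`. At the default `target_scale`
the PTV-initial volume is about 780 cc, inside the 600–1400 cc range
spanned by locally advanced rectal cancer cohorts; `target_scale`
modulates it strictly monotonically.

Deliberate simplifications: no CT texture or HU calibration (density is
relative electron density directly, so the CT-number conversion step of
the clinical workflow collapses to the identity); no bladder-filling
protocol analogue (bladder volume is a free parameter, defaulting to a
modestly filled ~130 cc); rigid anatomy. Tests passing on this phantom
demonstrate the planner's workflow logic and numerics, not clinical
performance on real CT data.

Default grid: 2.5 mm isotropic voxels over roughly 22 x 21 x 15 cm.
Clinical planning CTs use ~2 mm slices; the coarser grid keeps a full
planning run to minutes on one CPU while preserving every algorithmic
feature.

## Dose engine

Dose is computed with a primary-photon pencil-beam model: exponential
attenuation in water-equivalent radiological depth (ray-traced through
the density grid at a uniform step), inverse-square fall-off from a point
source at 1000 mm source–axis distance, and a Gaussian lateral penumbra
(sigma 3 mm). The default attenuation coefficient 0.04 cm^-1
approximates a 10 MV beam. There is no buildup region, no scatter
kernel, and no leaf transmission: depth dose decreases monotonically from
the surface, and dose is identically zero outside the scoring region.
These omissions are intentional — the model is *linear* in the fluence,
deterministic and fast, which is exactly what every downstream algorithm
(optimization, DVH, gamma, MCS) needs; absolute dosimetric realism is
not a goal.

The arc is a single full 360° rotation sampled at 72 control points (5°
spacing), collimator at 355° applied as an in-plane rotation of the
leaf-travel frame, isocentre at the target centroid. The machine output
is calibrated per phantom so one monitor unit of central-axis fluence
delivers 1 cGy at the isocentre averaged over the arc.

The influence operator is stored in factored form: per voxel and control
point, a transfer term (attenuation x inverse square) plus the voxel's
beam's-eye-view coordinates; dose is the transfer term times the
penumbra-blurred fluence interpolated at those coordinates. This keeps
the memory footprint at three dense voxel-by-control-point arrays
instead of an enormous voxel-by-beamlet sparse matrix, while single
influence columns remain materializable for testing.

## The automated workflow

`run_autoplan()` executes, in order and with a timed log: ROI-name
check; density mapping; virtual couch insertion (50 mm posterior slab,
density 0.3 — generic carbon-fibre-like values, as no protocol
parameters exist for the couch); derivation of the optimization ROIs
(bladder and small bowel with the target removed, and an anterior
"bowel-bag-like" control shell built by expanding the target 30 mm in
the abdominal direction minus a 3 mm gap ring — distances are config,
as the clinical protocol does not state them); isocentre placement;
objective construction; two fluence optimization passes; hotspot
extraction (voxels above 1.05 x prescription — a threshold chosen below
the D2 < 110% goal with headroom, as no clinical value is stated) and
three correction passes with an added hotspot maximum-dose objective;
coverage-constraint escalation; a final aperture-constrained
optimization; and leaf sequencing. The initial plan (45 Gy, on
PTV-initial) and the boost plan (5.4 Gy, on PTV-boost) are planned
independently; organ-at-risk goals are evaluated on the voxelwise plan
sum.

**Objectives.** The target receives a uniform objective at the
prescription, a minimum-dose objective just below it and a maximum-dose
cap just above; the body gets a near-maximum cap implementing the
D2 < 110% goal. Each organ-at-risk helper structure receives exactly one
dose fall-off objective: a per-voxel dose ceiling ramping linearly from
100% of the prescription at the target boundary to 30% at 20 mm
(distances from a Euclidean distance transform of the target). The
clinical Vx goals are additionally translated into max-DVH objectives on
the target-subtracted organs — dose levels scaled by the plan's share of
the summed prescription, allowed volumes tightened by a 0.75 headroom
factor so the plan sum retains margin — and zero-volume goals (V50 <= 0)
become strongly weighted absolute caps. With an empty goal list only the
target objectives are built.

**Two-stage optimization.** The "optimize two times / three times"
stages are warm-started projected-gradient runs (50 accepted iterations
each) on the free fluence, minimizing one-sided quadratic penalties
normalized per-ROI and per prescription-squared (so weights transfer
between the 45 Gy and 5.4 Gy plans). Accepted iterates never increase
the objective; a failed line search above the step-size floor terminates
the run as converged. After the penalty-driven stages, the plan is
converted to deliverable form — one aperture per control point — and
optimized *directly* in machine parameters: alternating projected
gradient on the per-control-point MU (segment-weight optimization) and
greedy single-bin leaf-edge moves accepted on their exact, incrementally
evaluated objective change. This mirrors the convert-and-continue
architecture of clinical optimizers, and it is why leaf sequencing at
the end is lossless: the plan dose *is* the deliverable dose.

**Escalation.** While the deliverable D93 of the target falls short of
the 98% coverage goal, the target minimum-dose weight is multiplied by
10 (at most 5 rounds; both values declared, not clinically derived), the
fluence re-optimized and the aperture projection repeated. Escalation is
judged on the deliverable dose because that is the dose the plan will
actually report.

## Evaluation and QA

DVHs are exact voxel-counting cumulative histograms at 0.05 Gy bins; Dx
is the largest dose received by at least x% of the volume, with linear
interpolation between bin edges (so closed-form cases are recovered to
within one bin width). The conformity index is TV_PIV^2 / (TV x PIV)
and the homogeneity index (D2 − D98) / prescription. (Published cohort
tables for this workflow print HI values near 0.7–0.8 that are
inconsistent with that formula applied to the same tables' D2/D98
columns, which give ~0.09; the formula is implemented as printed and
the discrepancy left unreconciled.)

Gamma analysis uses global normalization to the reference maximum, 3%/2
mm criteria, a 10% low-dose cutoff, a search radius of 3 x DTA sampled
at DTA/5 with trilinear interpolation of the evaluated dose; the
implementation returns the exact minimum gamma over that candidate set
(the search merely prunes candidates whose spatial term alone already
exceeds the incumbent). Self-QA recomputes the plan dose with the ray
step halved and the scoring grid shifted by half a voxel, resampled
back — a numerical-robustness probe standing in for phantom
measurement.

The modulation complexity score follows the VMAT adaptation of the
aperture-based complexity metric: per control point, aperture-area
variability (leaf-pair openings normalized by each pair's maximum over
the arc) times leaf-sequence variability (adjacent-leaf position
differences per bank, banks multiplied), MU-weighted over adjacent
control-point pairs. It is 1 for a fully open uniform arc, lower for
more modulated plans, and invariant to MU rescaling. Because no
leaf-speed or dose-rate limits are modelled, absolute MCS values are
optimistic relative to clinical deliveries.

The exact Wilcoxon signed-rank test drops zero differences, midranks
ties, and computes the two-sided p from the full sign-flip null
distribution (dynamic programming over doubled ranks) for n <= 25,
falling back to the tie-corrected normal approximation above.

## Numerical choices and degenerate inputs

* Margins are octant-wise scaled Euclidean dilations: a voxel joins the
  expansion iff its centre lies within the direction-dependent scaled
  distance of a source voxel centre; zero margins admit no motion along
  that direction, so all-zero margins are the identity.
* Empty masks are rejected by volume, centroid, DVH and expansion
  operations; grid mismatches are rejected everywhere.
* The optimizer treats a failed backtracking line search as convergence
  (with one-sided quadratic penalties the objective cannot increase on an
  accepted step); non-finite objectives abort with diagnostics.
* CI is defined as 0 (with a warning) when the prescription isodose is
  empty; MCS refuses zero-MU plans; the Wilcoxon test refuses all-zero
  differences.
* All randomness in the phantom flows from the single spec seed through
  a private RNG stream that leaves the session's RNG state untouched.

## Problem sizes

The packaged study conditions are the defaults everywhere: the seed-42
phantom at 2.5 mm / 72 control points, full prescriptions 45 + 5.4 Gy.
A complete automated run (both plans) takes roughly ten to fifteen
minutes on a single CPU; the unit-test suite exercises the same code paths on a
5 mm phantom and small closed-form fixtures in seconds. Oracle-
equivalence tests (expansion, gamma, DVH, Wilcoxon) run on grids up to
~40^3 where exhaustive enumeration is exact and fast.

## Known limitations

* The dose model omits buildup, scatter and transmission; absolute OAR
  doses and MCS values should be read as model quantities.
* Cohort-level published values (means over 26 patients on a commercial
  engine) are not reproducible here and are not targeted; the phantom
  run demonstrates goal attainment, not population statistics.
* One aperture per control point is assumed throughout sequencing; no
  machine dynamics (leaf speed, dose-rate) constrain the apertures.
* DICOM-RT interchange is out of scope; NRRD + JSON are the on-disk
  formats, with label maps bit-encoded to preserve overlapping ROIs.
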