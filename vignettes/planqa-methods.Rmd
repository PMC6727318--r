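---
title: "planqa: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{planqa: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(planqa)
```

## The problem

In an MRI-only prostate radiotherapy workflow the treatment plan is
calculated on a pseudo-CT — a HU volume synthesized from MRI — instead of
a planning CT. During clinical commissioning a conventional QA-CT is
still acquired, the plan is recalculated on it with the same fluences and
monitor units, and the two dose distributions are compared before the
plan is released for treatment. `planqa` implements that comparison as a
reproducible pipeline: geometric alignment, masking, a 3D gamma index, an
isocenter dose check, a fiducial-marker geometry check, and a checklist
report, with a synthetic phantom world standing in for clinical data.

## The comparison model

**Frame and grids.** Everything lives in DICOM-style LPS world
coordinates in millimetres. Grids are axis-aligned; the origin is the
*center* of voxel (0,0,0) and the bounding box extends half a voxel
beyond the extreme centers (NIfTI/DICOM sampling semantics). Oblique
acquisitions must be resampled upstream — the QA mathematics never needs
a rotation matrix, and refusing obliquity removes a silent error class.

**Alignment.** The evaluated dose grid is translated by the isocenter
difference so the two plan isocenters coincide. Full rigid or deformable
registration is deliberately out of scope: the clinical procedure keys
the dose comparison on the isocenters, and re-implementing a planning
system's auto-registration would be unverifiable here.

**Resampling.** Both doses are trilinearly interpolated onto one
isotropic lattice (default 1.5 mm) covering the *intersection* of the
two voxel-center bounding boxes — extrapolated dose is meaningless for
QA. The lattice is anchored so the reference isocenter falls exactly on
a lattice point; the isocenter dose check then reads a stored value
rather than an interpolated one, which stabilizes a 2 % tolerance
check. (The alternative anchorings — to either grid corner — are
equally defensible; anchoring to the isocenter is the one that protects
the tightest numeric check in the protocol.)

**Masking.** The body contour is taken from the QA-CT (the reference
side): threshold at −300 HU (the usual air/soft-tissue cut, exposed as a
parameter), largest 26-connected component (drops couch and cables),
per-slice hole filling (keeps rectal gas inside the body). A skin margin
(default 20 mm) is then removed by an *independent 2D erosion of each
axial slice* with a discrete disk of radius `round(margin / in-plane
spacing)` voxels, implemented via an exact per-slice Euclidean distance
transform (a pixel survives iff no background pixel lies within the disk
radius — mathematically identical to the structuring-element erosion,
but O(n) per slice). The margin exists because the external contour
differs systematically between CT and MRI-derived data; near the skin
the dose discrepancy is dominated by that contour difference, not by the
pseudo-CT HU quality being tested. The protocol's prose specifies 20 mm
while its checklist table prints 1.5 cm; the package follows the prose
and exposes the margin as `qa_tolerances(skin_margin_mm=)`. Finally,
voxels below 20 % of the maximum reference dose are excluded. Erosion is
performed at native CT resolution and the result transferred to the
comparison lattice by trilinear interpolation thresholded at 0.5.

**Gamma index.** For each masked reference voxel $r$,

$$\gamma(r) = \min_{r'} \sqrt{\left(\frac{D_e(r') - D_r(r)}{\frac{\delta}{100} D_{norm}}\right)^2
            + \left(\frac{\lVert r'-r\rVert}{\Delta}\right)^2}$$

* Normalization is **global** by default: $D_{norm}$ is the maximum
  reference dose within the mask. The protocol does not state its
  convention; global max is the one consistent with its "20 % of the
  maximum dose" threshold. Local normalization is available
  (`gamma_criteria(normalization = "local")`).
* The search runs over a cubic lattice of candidate points of pitch
  `search_step_mm` (default `min(spacing)/3`, i.e. 0.5 mm on the 1.5 mm
  lattice, capped at Δ/2) within radius 3Δ, with the evaluated dose
  sampled trilinearly. Sub-voxel search matters near steep gradients.
* Candidates are visited in order of increasing distance and the search
  stops as soon as the distance term alone reaches the current best γ —
  an exact pruning. `gamma_oracle()` is an independent, unpruned
  enumeration of the identical lattice used to verify the engine; both
  agree to floating point because min() over the same candidate set is
  order-independent.
* γ ≤ 1 passes, inclusive, with a 1e−9 epsilon so a case engineered to
  sit exactly on the boundary (uniform 2 % error at 2 %/2 mm gives
  γ ≡ 1) is not tipped by round-off. The same epsilon guards the
  isocenter ±2 % boundary.
* Voxels whose (non-pruned) candidates leave the evaluated grid are
  evaluated over the available candidates and flagged `edge_limited`
  rather than silently dropped; on the intersection lattice this is rare.
* Mean gamma is averaged over all evaluated voxels, not only failures.
  Whether the cohort statistic in the source protocol averages over
  threshold-excluded voxels is unstated; we average over the evaluation
  mask only.

**Isocenter dose.** Both doses are sampled trilinearly at the shared
isocenter; pass iff the difference is within ±2 % of the reference
(inclusive).

**Fiducial markers.** Three implanted gold seeds are localized on MRI
and on QA-CT. Because the scans are in different patient poses, absolute
positions are not comparable; the check compares each marker's *distance
to the marker-set centroid*, which is invariant under rigid motion. The
correspondence between the two sets is computed, not assumed: the
permutation minimizing the squared discrepancy between the two intra-set
pairwise distance matrices (exhaustive, n! with n ≤ 6), ties broken by
label order. A positional matching after centering was rejected — it is
defeated by exactly the rotations this metric is designed to tolerate.
Differences are kept signed (MRI − CT) with an absolute-value acceptance
rule at 1.0 mm, boundary inclusive (a clinical maximum of exactly
1.00 mm passed in the source protocol). The metric catches scale and
localization errors; it deliberately cannot (and should not) flag pure
rotations/translations.

**Checklist.** The report always contains the nine protocol rows in
order: six visual items (distortion correction, image transfer,
orientation/appearance, field of view, fiducial visibility, femoral
heads) supplied as operator flags, defaulting to *not assessed* which
blocks the overall pass; and three computed items — isocenter dose,
dose distribution (the 2 %/2 mm gamma against the > 90 % pass-rate rule;
the other criteria are reported as evidence only), and fiducial
positions. `overall_pass` is true iff every row passes. Cohort summaries
report mean, sample (n−1) SD, Bland–Altman limits mean ± 1.96 SD (the
standard definition; the protocol shows but does not define its
"levels"), RMS and range.

## The synthetic world

`make_phantom()` builds a digital pelvis: an elliptic-cylinder body of
soft tissue (0 HU; semi-axes 180 × 120 mm, length 200 mm — an adult
pelvis), two femoral-head spheres (r = 22 mm, +700 HU), an elliptic
pelvic-ring annulus (+500 HU), a prostate sphere (r = 22 mm, +30 HU) at
the isocenter, an optional rectal gas pocket (−1000 HU), in air, at
2.5 mm isotropic default spacing. Three fiducials sit ~10 mm from the
prostate center in a scalene triangle (pairwise ≥ 15 mm).

`make_pseudo_ct()` injects the error modes a pseudo-CT can exhibit:
soft-tissue and bone HU biases, per-slice contour jitter, and an
external 1 mm soft-tissue "skin" shell added by 2D dilation — emulating
the legacy algorithm variant whose erroneously generated layer led to
its removal partway through the source study. A 1 mm shell requires
≤ 1 mm in-plane voxels to be representable under the `round(r/spacing)`
disk radius rule; tests of this mode therefore use 1 mm in-plane
phantoms.

`toy_dose_engine()` maps HU to relative electron density by the standard
calibration linearization ρ = 1 + HU/1000 (clipped to [0, 2]) and, for
each of `n_beams` (default 7, IMRT-like) equispaced axial beams,
deposits `profile × exp(−μ_eff · WEPL)` where WEPL is the ρ-weighted ray
integral from the surface (step `min(spacing)/2`, trilinear sampling,
midpoint rule) and the aperture profile has erfc-smoothed edges
(half-width 35 mm, penumbra 3 mm, defaults sized to a prostate PTV).
μ_eff defaults to 0.005/mm, a megavoltage-like effective attenuation.
The **plan is normalized on the pseudo-CT** (prescription, default 2 Gy,
at the isocenter) and the QA-CT recalculation reuses the same raw-to-Gy
scale — the fixed-fluence/fixed-MU semantics of the clinical workflow.
Without that detail any isocenter dose comparison would trivially read
0 %.

The engine has no scatter, no buildup, no beam hardening: it exists to
make the QA metrics exercisable and *direction-correct* (denser tissue
attenuates more; an added skin layer lowers the pseudo-CT-planned dose
recalculated on CT, reproducing the sign of the legacy-variant effect),
not to be dosimetrically accurate. A green end-to-end test therefore
establishes that the pipeline's geometry, masking, statistics and
decision logic are correct on a controlled world — it does not validate
any clinical dose calculation, nor the pseudo-CT synthesis itself, which
is entirely out of scope.

Perturbation magnitudes have no quantitative basis in the source
protocol (only the skin-layer anecdote is reported); defaults were
chosen once to straddle the pass/fail boundaries — e.g. +40 HU tissue
bias ≈ −1.2 % isocenter dose (passes), 2 mm fiducial jitter fails the
1 mm rule in most replicates — and are not tuned against test outcomes.

## Numerical choices

* Trilinear sampling accepts points up to half a voxel beyond the
  extreme centers (clamped); beyond that an explicit outside-grid error.
* The gamma search-lattice radius is fixed at 3Δ for engine and oracle
  alike (identical candidate sets by construction). A true γ above 3 is
  reported at its truncated value; at such magnitudes the pass/fail
  decision is unaffected.
* NIfTI-1 geometry fields are float32; the writer additionally stores
  the exact LPS origin/spacing as doubles in the header's free-text
  `descrip` field, which the reader prefers, giving bit-exact round
  trips through this package while remaining valid NIfTI for other
  tools. The reader accepts any diagonal sform (flipping axes to keep
  spacing positive) and refuses oblique volumes.
* Erosion/dilation radii are rounded to whole voxels
  (`round(margin/spacing)`); sub-voxel margins on coarse grids are
  no-ops by design, and near-isotropic in-plane spacing is required.
* Report JSON is deterministic (fixed field order, no timestamps):
  identical bundle + configuration gives byte-identical files.

## Scope and limitations

* DICOM readers (CT series, RT Dose, RT Structure Set) are an optional
  extension in the build contract and are not implemented; core I/O is
  NIfTI + CSV + YAML. Writing DICOM, MRI simulation, plan optimization,
  deformable registration and couch modelling are non-goals.
* The fiducial check compares intra-set geometry only; automatic marker
  *detection* from images is out of scope.
* Test phantoms outside the acceptance suite are scaled down (coarser
  spacing, smaller anatomy) for speed; the acceptance tests exercise the
  stated default sizes.
* The cohort statistics of the source study (isocenter −0.04 ± 0.93 %,
  gamma pass 99.7 ± 0.5 % at 2 %/2 mm, fiducial RMS 0.42 mm) derive from
  30 clinical patients and cannot be reproduced by this package's
  synthetic world; the package reproduces the *procedure* and its
  decision behaviour, with property-based acceptance criteria instead.
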