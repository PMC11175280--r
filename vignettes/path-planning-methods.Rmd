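---
title: "Planning percutaneous ablation-needle paths from labeled CT volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning percutaneous ablation-needle paths from labeled CT volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The planning problem

Thermal ablation of a small liver tumor (diameter under 3 cm) destroys the
lesion by heating it through a needle inserted percutaneously. Preoperative
planning reduces, for a straight rigid needle, to choosing a skin entry point:
the trajectory is the segment from that entry point to the needle target,
taken here as the tumor's center of mass. `needleplan` automates this choice
from a labeled segmentation volume (skin, liver, tumor, and risk structures
such as vessels, bone and lung) by casting it as a constrained multi-objective
optimization over the finite set of skin-surface voxels.

Clinical rules split into two groups:

* **Hard constraints** — violating any one disqualifies a path:
  the needle must not touch a risk structure; the path length must be
  *strictly* less than the needle length `L`; and the insertion angle at the
  liver capsule must be at least a clinical threshold `angle_min`. A path
  that never crosses the capsule is also rejected: the needle has to traverse
  liver parenchyma to reach an intrahepatic target.
* **Soft constraints** — preferences traded off among admissible paths:
  clearance from risk structures `S1` (mm, larger is better), path length
  `S2` (mm, smaller is better), and capsule angle `S3` (degrees, larger is
  better, 90 = perpendicular insertion).

The skin voxels surviving the hard constraints form the *feasible insertion
region*; the planner then ranks that region in two independent ways.

## Weighted-sum scoring

Each raw soft value is min–max normalized over the feasible set onto a 0–10
scale, direction-aware so that 10 is always best. The scalar priority of a
candidate is the weighted sum

```
Pscore = Ps1 * a1 + Ps2 * a2 + Ps3 * a3
```

with non-negative weights normalized to sum one; the defaults are
`(0.3, 0.4, 0.3)` for (clearance, length, angle). A candidate that is
simultaneously best in all three criteria therefore scores exactly 10, the
top of the printed scale. Two normalization details are deliberate:

* A criterion whose value is constant over the feasible set (including the
  all-infinite clearance of a plan with no risk structure present) cannot
  discriminate and scores 10 for everyone, so a globally dominant candidate
  can still reach the ceiling of 10.
* Weights are renormalized only when they do not already sum to one within
  1e-9; this keeps the exact arithmetic of the default weights intact.

`rank_paths()` sorts by descending `Pscore` and recommends the top `k`
(default 3, so the operator can choose among a few good paths). Ties are
broken deterministically: higher clearance score, then shorter path, then
lexicographic entry voxel index.

Because every candidate path ends at the same tumor target, the whole-path
clearance saturates: for many entries the closest approach to a risk
structure happens near the target itself, so `S1` ties across a large part of
the feasible set. This is a property of the min-over-the-path definition, not
a defect; the normalization and tie-break rules above are written with it in
mind.

## Pareto screening

Weight choices are subjective, so the planner also offers a weight-free
screen. The three objectives are combined in pairs; in each pairwise
coordinate system the non-dominated candidates form a two-objective Pareto
front, and the global result is the set intersection of the per-pair fronts.
Domination is *weak-plus-strict*: `q` dominates `p` when `q` is at least as
good in both objectives and strictly better in at least one — ties alone
never dominate, and duplicates of a front point are all retained. Fronts are
computed by sort-and-scan in O(n log n) and are validated in the test suite
against an O(n²) pairwise oracle.

Two design choices were genuinely open:

* **Degenerate pairs.** If an objective is constant across the feasible set,
  any pair containing it degenerates: under weak-plus-strict domination its
  front collapses to the argmax of the other objective, and the intersection
  becomes spuriously empty or a singleton even when the two informative
  objectives exhibit a rich trade-off. Such pairs carry no trade-off
  information, so they are excluded from the intersection (the mirror image
  of the normalization rule above). If no discriminative pair remains, every
  feasible candidate is reported. Members of the intersection are always
  three-objective Pareto-optimal — pairwise non-domination in every active
  pair implies no candidate beats them in all three objectives — and the test
  suite asserts this against a three-objective brute-force oracle.
* **Empty intersection.** Three pairwise fronts need not share a member. In
  that case the result carries a fallback flag and reports the per-pair
  fronts together with the weighted-sum top-k, rather than failing.

Interactive screening (`dominators_of()`, CLI `screen`) evaluates a
clinician-chosen entry point and lists every feasible candidate that
dominates it in a chosen pair (default: path length vs clearance), sorted by
weighted score. A query on that pair's front gets an empty answer by
definition. Note that the *weighted-sum* top path is guaranteed non-dominated
in the full three-objective sense but not in every pair: a candidate with
equal clearance and shorter length may pairwise-dominate it while losing
badly on the third objective.

## Geometry kernels and numerical choices

All geometry is computed in world millimetres (voxel centers at
`origin + spacing * index`, 0-based indices); nothing depends on voxel-count
arithmetic, so anisotropic spacing is handled throughout.

* **Distance field.** `distance_transform()` computes the exact anisotropic
  Euclidean distance from every voxel center to the nearest structure voxel
  center via three separable lower-envelope passes (compiled code). The path
  clearance `S1` is the minimum of the trilinearly interpolated field over
  the sampled path.
* **Collision hard constraint.** Point-sampling a segment can step over the
  corner of a voxel, and a verdict that flips under refinement would make the
  feasible set depend on an arbitrary step size. The hard constraint
  therefore uses an exact voxel traversal (Amanatides–Woo): the path is
  rejected if it passes through any risk voxel's box at all. The
  general-purpose `segment_intersects()` keeps the simpler sampled test
  (default step: half the minimum spacing) for queries where a step-dependent
  answer is acceptable; the suite verifies that refining its step only
  changes verdicts within half a voxel diagonal of a surface.
* **Capsule crossing and angle.** The crossing is the first entry of the
  path into the rasterized liver, refined by bisection to 0.1 mm; each
  candidate's bisection trajectory is independent of the rest of the batch,
  so batch and single-path evaluations agree bit-for-bit. The capsule normal
  is the gradient of a Gaussian-smoothed mask indicator (scale: twice the
  maximum spacing, configurable), evaluated locally and oriented outward. The
  insertion angle is measured against the tangent plane,
  `90° − angle(direction, normal)` using the absolute cosine, so 90° means
  perpendicular insertion and the normal's sign convention is irrelevant.
  Against analytic slabs and spheres the rasterized-mask angle is accurate to
  about 2–3 degrees, which is far finer than the granularity of clinical
  angle thresholds.
* **Tumor target.** The unweighted centroid of tumor voxel centers; a
  multi-component tumor mask yields the centroid of the union with a warning.

Key tunables, all in `planning_config()`: needle length `L` (default 150 mm —
a long ablation needle; set the actual hardware), `angle_min` (default 20°;
the appropriate clinical threshold is institution-specific and deliberately
configurable), soft weights (default 0.3/0.4/0.3), sampling step (default
half the minimum voxel spacing), skin stride (enumeration subsampling,
default 1), and the set of risk roles (default vessel, bone, lung; liver and
tumor are never risk structures).

## The synthetic phantom

`generate_phantom()` rasterizes an analytic scene — a closed ellipsoidal skin
shell, a liver ellipsoid, a spherical tumor of default radius 10 mm (the
sub-3-cm regime the planner targets), a rib-like bone slab between skin and
liver, and an intrahepatic vessel near the tumor — onto a 64³ grid at 2.5 mm
isotropic spacing by default. Generation is deterministic given the
configuration; `random_phantom_config(seed)` draws randomized variants for
property-style testing. The analytic truth (tumor centroid, primitive
geometry) accompanies every volume, and rasterization is accurate to half a
voxel diagonal by construction.

The phantom emulates exactly what the planner consumes: label geometry with
realistic scales and genuine obstructions. It does **not** emulate CT
intensities, segmentation errors, organ deformation, respiratory motion, or
the irregular shapes of real anatomy. Tests passing on phantoms therefore
validate the planning machinery — constraint logic, scoring, screening,
geometry — not the upstream segmentation, and say nothing about clinical
adequacy of a specific plan on a real patient.

Problem sizes used by the test suite and the reproduction script — 64³ grids,
skin strides of 7–19 (several hundred to a thousand candidates), brute-force
oracles up to n = 2000 — were chosen so a full run completes in a few minutes
on one core while still exercising every code path at clinically plausible
scales.

## File formats and persistence

Volumes are read and written in NIfTI (via RNifti), MetaImage and NRRD;
MetaImage and NRRD are written uncompressed with 32-bit little-endian
integers. Only axis-aligned grids are accepted; axes stored with a negative
scale are flipped on read. NIfTI stores geometry as 32-bit floats, so spacing
and origin round-trip to about 1e-7 relative accuracy there, while the
text-header formats round-trip exactly. Floating-point voxel types are
rejected: the planner's contract is an integer label map. DICOM series are
out of scope; convert them to a research format first.

Planning records (volume metadata, configuration snapshot, recommended paths
with raw and normalized scores, Pareto summary, interactive evaluations) are
persisted in a single-file JSON record store with monotone ids, atomic
writes, and 17-significant-digit float serialization, so a reloaded record
reproduces every stored number bit-exactly. Records are immutable once saved.

## Known limitations

* The tumor is abstracted to a single target point; ablation-zone coverage,
  conformality for irregular tumors, and multi-needle placement are not
  modeled.
* Treatment parameters (power, duration) and coagulation-zone prediction are
  out of scope.
* Organ motion and deformation (breathing, needle–tissue interaction) are
  ignored; the plan is only as current as the input volume.
* Feasibility is binary at the voxel level: a path clearing a vessel by a
  fraction of a millimetre is feasible (its low clearance score penalizes it
  in the ranking); institutions wanting a hard safety margin should encode it
  by dilating risk masks upstream.
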