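---
title: "Navigation planning for secondary zygoma reduction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Navigation planning for secondary zygoma reduction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnrp)
```

## The clinical problem and its geometric core

A secondarily dislocated zygoma has fused fracture lines: nothing on the
bone says where it belongs. Computer-assisted planning solves this by
simulating the reduction on CT-derived surface meshes and carrying the plan
into surgery with an optical navigation system. Strip away the hardware and
what remains is rigid geometry: one transform `T` in SE(3) maps every point
`p_D` on the dislocated fragment to its planned position `p_R = T p_D`, and
its inverse pulls planned screw holes back onto the dislocated bone,
`p_D = T^{-1} p_R`. Marks pushed forward through `T` are *free navigation
reference points* (FNRPs): intraoperative targets that let the surgeon pick
reference marks freely during surgery instead of committing to predetermined
ones, and still know, by probing, exactly how far the fragment is from its
planned pose. This package implements that core — estimation of `T`, the
two transport operations, the probing procedure, and the error analyses —
with a synthetic phantom so every step is testable against known ground
truth.

## Estimating the reduction transform

`reduction_fit()` estimates `T` from two point clouds sampling the same
fragment surface (dislocated and planned configuration):

1. **Coarse alignment** — a closed-form least-squares rigid fit to ≥ 3
   paired landmarks (`landmark_fit()`): centre both sets, take the SVD of
   the 3 × 3 cross-covariance, and correct the determinant so only proper
   rotations are admitted. Reflection-requiring pairings therefore resolve
   to the best rigid motion, never a mirror. Collinear sources are refused
   (the rotation about the common line is unidentifiable) naming the
   degenerate direction. The reported RMS is the fiducial registration
   error.
2. **Fine alignment** — point-to-point ICP: match each transformed source
   point to its nearest target point, optionally discard gated/trimmed
   correspondences, solve the closed-form rigid update on the
   correspondences, repeat.

The ICP variant is deliberately the classic point-to-point form;
point-to-plane is out of scope. Defaults (`icp_params()`): at most 100
iterations; convergence when the RMS residual changes by `< 1e-6` mm —
tight, because inputs are millimetre-scale bone surfaces and the noiseless
phantom should be recovered essentially exactly; trimming off (`trim_fraction
= 0`), exposed because real marker clouds contain outliers, at the cost of
the monotone-RMS guarantee; no correspondence distance gate; clouds above
5000 points are subsampled under a recorded seed. Nearest-neighbour ties
break towards the lowest target index, so runs are bit-reproducible. With
trimming off, the recorded `rms_trace` is non-increasing (each rigid update
minimises the residual over the current correspondences, and re-matching can
only shorten each point's distance); the suite asserts this on every run it
performs.

A fit that fails to converge, or whose final RMS exceeds `rms_threshold`
(default 1 mm), is refused rather than returned: a silently bad `T` would
corrupt every FNRP and drilling target derived from it.

## FNRPs, back-calculation and the probing procedure

`generate_fnrps()` applies `T` to each registered mark; `predict(fit, x,
direction = "dislocate")` applies the analytic inverse `[R', -R't]`, so the
forward/backward round trip is exact to machine precision — the suite
checks `1e-9` mm over a thousand random transforms. At least three
non-collinear marks are needed to pin down a 3-D pose, so fewer than three
draws a warning.

The fit carries a `reduced` state flag. Surgical manipulation breaks the
bone-to-image registration, so marks must be registered *before* the
fragment is freed; once a plan is flagged with `mark_reduced()`, further
FNRP generation on it is refused rather than silently producing invalid
references.

`probe_readings()` reports, per mark, the offset vector and distance from
its FNRP — what the navigation display shows. `pose_from_probes()` makes
the implicit explicit: three or more probed marks are a landmark-fit problem
whose solution is the fragment's current rigid pose; comparing it with `T`
quantifies residual malposition. When reporting the *translation error* of
such a pose estimate, the package's tests evaluate the displacement at the
fragment's geometric centre, not the difference of matrix translation
columns: the translation column depends on where the arbitrary image origin
sits (tens of millimetres from the fragment for a CT frame), which would
triple-count rotation noise into a quantity that is supposed to describe
the fragment.

Probe-tip depth — a tip that cannot reach the bottom of a deep hole reads
systematically shallow — is modelled as an optional constant `depth_bias`
vector in `simulate_probe_readings()`, default zero.

## Error evaluation

**Drilling deviation** is the Euclidean distance between a
drilled-and-registered screw hole and its planned position, collected per
fracture site in a `deviation_table` with per-site means, a grand mean and
grand standard deviation.

**Global reduction error** (`global_error()`) follows the whole-procedure
analysis: align the postoperative mesh to the preoperative plan by ICP on
the un-operated region only (centroid pre-alignment absorbs the scanner
frame translation), then estimate the residual rigid transform between the
planned and achieved zygoma clouds; the displacement is the distance between
the two geometric centres, the rotation its Euler decomposition. The
geometric centre is the unweighted vertex centroid of the labelled region;
an area-weighted surface centroid is available (`weight = "area"`) since
"centre" of a surface mesh is otherwise convention-dependent.

Three reporting conventions deserve justification:

* **Euler convention.** Angles are extrinsic fixed-axis X-Y-Z degrees,
  `R = Rz(rz) Ry(ry) Rx(rx)`, chosen for unambiguous reproducibility and
  used everywhere. For the sub-degree rotations typical of navigation error
  reports, all common conventions agree to well under 0.001°, so the choice
  does not affect reported summaries. At gimbal lock (`ry = ±90°`) `rx`
  absorbs the free angle, `rz` is set to zero and the result is flagged.
* **Standard-deviation denominator.** Summaries default to the population
  (divide-by-n) form. Recomputing the bundled reference series' printed
  spread values succeeds with the population denominator (0.380 for both
  the 72-hole grand SD and the displacement column; 0.599 and 0.427 for the
  x- and z-axis columns) and fails with n−1 (≈ 0.416 for displacement), so
  that is the convention such series use; the sample form remains available
  via `sd_type`.
* **Absolute values.** Per-axis rotations are signed in the input, but only
  absolute-value means and SDs are summarised: sign conventions do not
  survive between navigation systems, and the absolute summaries are what
  the spreads above reproduce. The bundled series' y-axis spread is the one
  cell that does not recompute from its printed per-case values (0.543
  versus 0.548 printed, under every standard convention tried — most likely
  rounding of unprinted source data), and it is accordingly not asserted
  anywhere.

## The synthetic phantom

`make_phantom()` builds a stylised skull: an ellipsoid shell (semi-axes
70 × 90 × 80 mm; x = left, y = posterior, z = superior, right-handed — the
frame is arbitrary, as a CT scanner's is) carrying a malar-like protrusion,
brow/occiput/mastoid bumps and a low-frequency radial texture
(~30 mm wavelength, ~1.6 mm amplitude). The texture matters: real bone is
featured everywhere, and a smooth shell would give surface ICP almost no
rotational gradient, making registration degenerate for reasons that have
nothing to do with the method. The zygoma region is the patch within 30° of
the malar direction, separated from the fixed skull by a 4° annular gap that
emulates the deliberately widened fracture line — so the fragment shares no
vertices with the fixed region, and the fixed region is bit-identical
between the planned and dislocated phantoms while the zygoma differs exactly
by the ground-truth transform.

Study conditions baked into the defaults: three anatomical registration
landmarks (nasion-like and two suture-like points); three surface marks at
zygomatico-frontal, infra-orbital and buttress-like sites; twelve screw
holes per zygoma (three plate sites × four holes); dislocations up to 10°
and 8 mm (15°/10 mm in the recovery tests); fiducial and probe picking noise
0.3 mm isotropic Gaussian, a typical optical-tracker figure adopted because
the source setting does not quantify it; drilling scatter 0.579 mm, the
sigma whose Maxwell mean `2σ√(2/π)` equals the 0.924 mm mean drilling
deviation of the reference series. All randomness flows through one seed per
call, restoring the caller's RNG state.

What the phantom does **not** emulate — and hence what passing tests do not
show: anatomical skull shape, CT acquisition and segmentation error, mesh
artefacts of real reconstructions, soft-tissue traction, or tracker-specific
noise structure (the noise here is isotropic and Gaussian). Conclusions from
the phantom are about the geometry pipeline, not about clinical accuracy.

## Numerical choices and degenerate inputs

* Transforms are validated on construction: orthonormality to `1e-9`,
  determinant +1, exact `[0 0 0 1]` bottom row; composition
  re-orthonormalises (polar projection via SVD) when drift exceeds `1e-9`.
  Inversion is analytic, so inverses are exactly rigid.
* Nearest neighbours are computed by blocked vectorised distance expansion
  (`|q|² + |r|² − 2 q·r` through BLAS), 512 query rows per block to bound
  memory; ties to the lowest index.
* STL files store three independent float32 vertices per facet; reading
  merges coincident vertices at `1e-6` mm to recover topology. Binary
  detection trusts the `84 + 50·n` size signature, not the `solid` keyword.
  Readers of every format reject malformed content with the offending line
  rather than coercing.
* Empty point sets transform to empty sets; empty regions, collinear
  landmark sets, non-rigid matrices and unlabelled faces are errors.

## Known limitations

* Point-to-point ICP at the phantom's mesh resolution captures rotational
  frame offsets of a few degrees; grossly rotated frames need a landmark
  initialisation (`global_error(align_init = )`, or `init` in `icp()`).
  Denser sampling or point-to-plane correspondences would widen the basin
  but are out of scope.
* The estimator family is strictly rigid — no scaling, no deformation —
  which is correct for bone but means soft-tissue effects are invisible.
* Pose recovery from exactly three probed marks is minimal: one noisy probe
  strongly influences the estimate. The machinery accepts any number of
  marks; more is better.

## Problem sizes used by the test suite

Unit tests run on a 40 × 60-resolution phantom (~2400 vertices, ~90 on the
zygoma); the acceptance checks use the default 64 × 96 resolution (~6000
vertices, ≥ 200 on the zygoma), 1000-transform round-trip sweeps, 50
landmark-fit instances against a 4000-rotation quaternion grid, 100 seeded
probing replicates and 50 synthetic 72-hole drilling tables. The full suite
and the acceptance script each complete in well under a minute on one CPU.
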