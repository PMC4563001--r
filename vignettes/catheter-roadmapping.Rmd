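---
title: "Catheter-based 2D/3D registration for continuous roadmapping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Catheter-based 2D/3D registration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cathreg)
```

## The problem

During transcatheter arterial chemoembolization (TACE) and similar abdominal
interventions, the interventionalist steers a catheter through the hepatic
arteries under single-plane fluoroscopy. The vessels themselves are invisible
without contrast agent, and respiratory motion continuously displaces the
liver, so a static overlay of a perioperative 3D rotational angiography
(3DRA) vessel model drifts off the anatomy within one breath. cathreg
registers the 3D vessel-tree centerline to the *catheter* centerline visible
in every fluoroscopic frame — the only always-visible vascular structure —
so the roadmap can follow the motion frame by frame without contrast.

The registration has two stages:

1. **Shape-based candidate selection.** The catheter must lie inside some
   root-ward vessel path of the tree. Candidate paths are ranked by a
   tangent-based shape similarity between the catheter and the projected
   vessel, and only the best `k` (default 5) leaf paths are registered.
2. **5-DOF rigid registration.** For each candidate, a rigid transform —
   three rotations plus two detector-plane translations — is estimated by
   minimizing a weighted closest-point metric between the catheter points
   and the projected vessel path. The candidate/pose pair with the smallest
   metric wins.

## Geometry and the pose

Points live in three frames: the vessel-tree frame (3DRA), the world frame
with its origin at the C-arm iso-center, and the 2D fluoroscopic image. The
cone-beam projection is a pinhole map with source-to-isocenter distance SOD
(default 810 mm) and source-to-detector distance SID (default 1200 mm); at
the iso-center plane the magnification is SID/SOD ≈ 1.48.

The unknown alignment decomposes as

```
T_w<-3DRA = T_w<-det . T_trans(x, y) . T_det<-w . T_rot(alpha, beta, gamma)
```

so the rotation acts in the vessel-tree frame and the translation along the
detector axes, where respiratory motion lives. Translation along the
projection axis changes the projection only via the ~1/SOD magnification
derivative, is unrecoverable from a single view, and is excluded — the pose
has five parameters. Euler angles follow a fixed documented convention
(`Rz(gamma) Ry(beta) Rx(alpha)`, degrees); since the angles are search
variables rather than reported quantities, any fixed convention is
equivalent.

The rotation **center** is genuinely open configuration: `register_catheter()`
defaults to the tree's bounding-box centroid, which decouples rotation from
translation and is the natural choice for interactive use and for local
optimization. The simulation protocol (`run_experiment()`) instead rotates
the brute-force search about the corner of a typical 250 mm 3DRA volume
centered on the tree, for two reasons. First, in clinical volumes the
rotation of the pose acts about the image origin, which sits at a corner,
far from the vessels. Second — and measurably — a distant center turns the
angle dimensions of the grid search into fine translation knobs: each of the
343 angle combinations of an iteration displaces the tree by a few
millimetres, so the coarse iterations sweep translation space much more
densely than their 7 × 7 translation grid alone, and the search finds the
correct basin far more reliably (in our probes this roughly halves the
median tip error of the grid search). The local Powell optimizer, by
contrast, is better conditioned with the tree-local centroid and keeps it.

## Shape similarity

The similarity of a candidate path starting at node `p` is the integral over
the catheter arc of the dot product between the catheter's unit tangent and
the projected vessel's unit tangent at the same arc length from the
candidate tip, projected under the *identity* pose. It is discretized as a
sum over catheter segments with per-segment constant tangents; no splines.
Because only tangents enter, the score ignores the distance between the two
curves (translation-invariant), and its maximum is the catheter length.
Catheter arcs beyond the projected vessel's end contribute zero, penalizing
candidates that are too short without rejecting them; dot products are
signed, so antiparallel geometry scores negative. Per leaf, every node of
the (resampled) leaf path is scanned as a candidate tip and the maximum is
kept, ties breaking toward the leaf. Leaves whose best paths traverse the
identical node sequence over one catheter length keep only the
highest-scoring representative.

## The registration metric

The catheter tip is matched to the closest point of the projected candidate
path; each subsequent catheter point is matched within a window that starts
at the previous match and extends at most `d_max` mm root-ward along the
projected path, which preserves the continuity of the correspondence and
bounds the cost. Distances are weighted by a tip-centered Gaussian with
offset, `W(x) = lambda + (1 - lambda) exp(-x^2 / (2 sigma^2))`, because
accuracy near the tip matters most. Defaults are the settings found optimal
per optimizer on clinical data: brute force `lambda = 0.1, sigma = 80,
d_max = 20`; Powell `lambda = 0.2, sigma = 20, d_max = 40`; both at 3 mm
sampling.

Two implementation points matter numerically:

* **Interpolated matching.** Catheter points are matched to the linearly
  interpolated projected centerline (point-to-segment within the arc
  window), not to its discrete vertices. With vertex matching the metric is
  rippled at the vertex spacing; when catheter and vessel share a
  discretization (exactly the simulation setting) the true minimum becomes
  a needle a millimetre wide surrounded by slide aliases one vertex apart,
  and no coarse-to-fine search can find it reliably. Interpolation makes
  the metric piecewise-smooth in the pose and restores wide basins. The
  vertex-level operations (`tip_distance()`, `windowed_distance()`) remain
  available and tested.
* **Full leaf paths.** The whole candidate leaf path is registered; the tip
  term is free to match anywhere along it. Truncating the path at the
  shape-selection argmax would couple the argmax's one-or-two-node jitter
  into a longitudinal registration shift of several millimetres.
* Arc lengths for the weight argument are measured along the 2D catheter
  polyline; the window bound `d_max` along the 2D projected vessel. Ties in
  any arg-min break toward the more distal (smaller-index) point.

## Optimizers

**Brute force** is a multi-resolution grid search: 7 iterations, each a full
7^5 grid spanning the incumbent ± the current half-intervals (initially
±50 mm for x, y and ±7° for the angles), halving the intervals per
iteration. The grid always contains its center, so the incumbent metric is
non-increasing; the final grid half-interval is 50 · 0.5^6 ≈ 0.78 mm. Optima
outside the initial intervals clamp to the searched region. The inner loop
(7 · 7^5 ≈ 118k metric evaluations per candidate) is compiled (Rcpp); a
plain-R reference of both the metric and the grid refinement is kept and
cross-checked in the tests.

**Powell** is a two-stage direction-set method: stage 1 minimizes over the
in-plane translation only, stage 2 over all five parameters from the stage-1
result. No installed R package provides Powell's direction-set method, so it
is implemented here with Brent line minimizations (`stats::optimize`);
tolerances are 1e-4 mm on the metric, 1e-3 mm/deg on parameters, at most
2000 evaluations per stage — a stage costs two orders of magnitude less than
the brute force. As a local method it can converge to local minima; the
experiment tables show the resulting heavy tail, while its median accuracy
remains good.

## The synthetic data generator

No clinical data accompany the package, so `generate_tree()` produces
hepatic-artery-like trees: a near-straight aorta trunk (100 mm, 0.1°/mm bow)
rooted at its caudal end; a sharp ostium takeoff (60–100°) into the hepatic
main branch — the celiac/hepatic turn every catheter path contains, which
anchors the registration longitudinally; a 40 mm childless aorta
continuation; and recursive binary branching (probability 0.9, up to 4
generations, segments 20–45 mm, opening angles 25–70°). Branch segments
bend as smooth constant-curvature arcs with per-segment curvature drawn
from 0.5–2.5°/mm (radii ≈ 23–115 mm) plus 0.1°/mm jitter. We model smooth
arcs rather than a white-noise random walk of the direction because
skeletonized vessel centerlines are smooth, low-frequency curves; per-step
direction noise has the wrong spatial spectrum (jagged at the sampling
scale) and materially distorts the registration landscape. Trees are
recentered so the bounding-box centroid sits at the world iso-center.

`simulate_catheter()` extracts the root-ward path from a chosen tip node,
projects it under a ground-truth transform (the 5-DOF pose plus a physical
depth offset `z`, which exists even though registration never searches it),
and smooths the 2D projection along arc length with a Gaussian of standard
deviation `sigma_simu` to emulate a catheter that stretches the vessel.
Boundary handling reflects the coordinates about the endpoints so the tip is
preserved exactly; the ground-truth projected tip is recorded before
smoothing. `random_pose()` draws ground-truth transforms from three named
sets (slight / moderate / large) whose translation, rotation and smoothing
ranges grow in magnitude; the y (craniocaudal) translation ranges are the
largest, matching respiratory motion.

What the generator does **not** emulate: real segmentation artifacts
(spurs, gaps, missed branches, incomplete aortas), vessel lumen and radius,
anatomical variants of the celiac axis, non-rigid deformation of the liver
between acquisition and intervention, and catheter mechanics (the smoothing
is a geometric surrogate for vessel stretching). Passing the simulation
study therefore demonstrates the geometric correctness and search
robustness of the method under rigid motion with depth and smoothing
perturbations — not clinical-grade accuracy on real images.

## The simulation experiment

`run_experiment()` runs the full protocol per case: generate a seeded tree,
resample it at the working 3 mm spacing, pick a tip node at least 120 mm of
arc from the root (so the simulated catheter has realistic proximal
extent), draw a ground-truth transform from the chosen set, simulate the
catheter, register it back with each requested optimizer, and measure the
tip error. The catheter is resampled at the 3 mm sampling in image mm (as
an annotated catheter would be); the tree is not resampled a second time —
resampling shortens arc lengths slightly (corner cutting), and a second
pass would shift catheter and candidate paths against each other by up to a
millimetre.

The error `e_d` is the Euclidean distance between the known 3D tip
projected under the true transform and the same point projected under the
estimated transform, with longitudinal and orthogonal components `l_d`,
`o_d` taken along and across the catheter direction at the true tip
(`e_d^2 = l_d^2 + o_d^2`). Every random draw flows through the single
experiment seed; rerunning reproduces the table bit for bit.

Problem sizes used by the packaged tests and the acceptance script: trees
of roughly 200–350 nodes at 3 mm steps, catheters of 200–350 mm image
length, 102–120 cases pooled over the three perturbation sets with
`sigma_simu = 0`, both optimizers — a few minutes on one CPU.

```{r, eval = FALSE}
experiment <- run_experiment(n_cases = 102,
                             optimizers = c("brute_force", "powell"),
                             sigma_simu = 0, seed = 1)
autoplot(experiment)
```

## Evaluation utilities

`tip_errors()` decomposes a registered-vs-true projected tip displacement.
`paired_vessel_distance()` implements the clinical surrogate metric: the
symmetric closest-point distance between paired 2D vessel centerlines
(observed vs registered-projected), restricted to a 30 mm disk around the
catheter tip, excluding source samples whose closest match lands on an
endpoint of the other polyline (a truncation artifact, not a
correspondence); direction means are averaged per pair, pairs averaged per
image. `distance_by_tip_bucket()` aggregates the same distances by distance
from the tip. `parameter_sweep()` evaluates a scoring function over a full
factorial of the metric parameters (default grids: lambda 0–0.3, sigma
20–100, d_max 10–50 mm) with an optional leave-one-out mode; pairing of
vessels is supplied by the caller — manual pairing and visual grading are
out of scope.

## Numerical choices and degenerate inputs

* Points at or behind the X-ray source plane (depth ≤ 0) are rejected with
  the offending index; the compiled optimizers treat such poses as
  infinitely bad rather than erroring mid-search.
* Resampling retains first and last points; the final segment may be
  shorter than the spacing. Resampling is exactly idempotent only when
  vertices already sit at spacing multiples — on curves the resampled
  polyline is shorter than the original (chords cut corners), so a second
  pass drifts by a bounded fraction of the spacing.
* Tangents at interior vertices use the outgoing (proximal-side) segment.
* Branch points are never removed by tree resampling; interior run nodes
  get derived ids.
* In the tie between equally scoring candidates or grid points, the first
  in deterministic evaluation order wins, making every run reproducible.

## Known limitations

* The brute-force schedule commits to a basin within two or three
  iterations; on self-similar vasculature (a long straight aorta, sibling
  branches of similar shape) the coarse first grid can rank a wrong basin
  ahead of the true one, which the remaining iterations cannot leave. The
  distant rotation center mitigates but does not eliminate this; the
  experiment tables carry the resulting tail.
* Registration is rigid per frame; liver and catheter deformation are not
  modeled, and each frame is registered independently of its predecessors.
* The shape similarity scores candidates under the identity pose, so it
  assumes vessel orientation changes little between the 3D acquisition and
  the current frame — valid for respiratory motion, not for large patient
  repositioning.
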