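---
title: "Morphological tree clones: models, distances and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphological tree clones: models, distances and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treeclone)
```

## Overview

`treeclone` fits a stochastic tree growth simulator to a target tree given
as a cylinder table, by minimising a projection-tomography distance
between empirical morphology distributions, and then generates
"morphological clones": stochastic trees sharing the target's coarse
structure while varying in fine detail. This vignette records the models,
the conventions, and the design decisions behind the implementation — in
particular the points where a choice had to be made among several
defensible options.

## Cylinder trees and Gravelius orders

A tree is an ordered table of circular cylinders (start point, unit axis,
length, radius) linked by parent indices into a single rooted structure.
Two annotations organise cylinders into *branches*: a branch id and a
Gravelius order `w`, with the trunk at `w = 0` and laterals incrementing
the order. Imported QSM-style tables are snapshots without growth history,
so orders are extracted with the *thickest-branch rule*: at every
junction, the child with the largest radius continues the parent's branch
and order, the thinner children become laterals of order `w + 1`.

Design decisions:

* **Ties** in radius are broken toward the lowest row index. Any
  deterministic rule is acceptable in the measure-zero tie case; this one
  is the limit of "thickest continues" and keeps the assignment stable
  under row reordering of the non-tied part.
* Orders are **capped** at a configurable `w_max` (default 10) to guard
  against pathological inputs; capped cylinders keep `w_max`.
* The CSV dialect (9 significant digits, 0-based parent with −1 root,
  z-up, metres) mirrors common QSM cylinder exports so that real QSMs can
  be converted with a one-off script. Written files read back
  field-for-field identical, which is what makes the simulator's
  bit-reproducibility contract testable at the file level.
* Child-start-on-parent-end is validated only for simulated trees
  (tolerance `1e-6` m); imported QSMs are exempt because reconstruction
  noise routinely violates it.

## Structural feature tables

Branch tables `B^w` carry one row per branch: inclination `β` (degrees,
against the supporting parent segment), azimuth `α` (degrees around the
parent segment axis), total length `L_t`, initial radius `R_f`, and
attachment length `L_a` (distance along the parent branch from its start
to the attachment point, through the supporting segment). Segment tables
`S^w` carry one row per cylinder: radius `R`, along-branch distance `L`
(measured to the segment *base*, so a branch's first segment has `L = 0`),
horizontal turn `γ`, and vertical turn `ζ`, each relative to the parent
segment. Tables of one kind may be merged across orders; branch and
segment tables differ in dimension and are never merged together.

Angular conventions the data do not fix by themselves:

* **Trunk frame.** The trunk has no parent, so its `β` is measured from
  global vertical and its `α` from global `+x`. Any fixed frame works: the
  distance below is insensitive to a global rotation about z, because all
  angle features are *relative* except the trunk's own row.
* **`α` reference.** The azimuth zero is the projection of global `+x`
  onto the plane normal to the parent axis (`+y` when the parent axis is
  within `1e-6` of `+x`). Fits are in any case determined only up to a
  rotation about the z-axis, so the absolute reference is immaterial.
* **`ζ`** is the unsigned difference of the two segments' elevation
  angles, in `[0, 180]`. "Vertical projection angle" admits several
  readings; the elevation difference is the one that is invariant under
  rotation about z, consistent with the rotational ambiguity above.
* **Degenerate `γ`** (a segment whose axis has horizontal norm below
  `1e-9`, i.e. a vertical segment) is defined as 0, the limit of a nearly
  vertical segment, avoiding NaNs in otherwise valid tables.

## The structural distance

For a table pair `(U_m, U_d)` the distance is

`D_S(U_m, U_d) = (1/n) Σ_i K[P_1D(U_m, L_i), P_1D(U_d, L_i)]`,

the mean over `n` line directions of the two-sample Kolmogorov–Smirnov
statistic between the projections of the two tables onto each line. It
lies in `[0, 1]`, vanishes exactly on identical tables, and is symmetric
when both sides share the direction set. With several table pairs the
objective is the unweighted mean of their distances.

Numerical and design choices:

* **Directions** are deterministic: a Halton low-discrepancy sequence in
  the unit cube (prime bases 2, 3, 5, …), mapped coordinate-wise through
  the standard-normal inverse CDF and normalised. By the spherical
  symmetry of the Gaussian this covers the sphere asymptotically
  uniformly, and more evenly at finite `n` than pseudo-random draws. The
  feature spaces here have 4–5 dimensions, well within the range where
  Halton sequences are well behaved. Antipodal directions are not
  deduplicated: the KS statistic of a negated projection equals that of
  the original, so duplicates are harmless redundancy.
* **Standardisation.** Feature columns mix degrees and metres, so before
  projection each column is centred by the pooled median and scaled by
  the pooled IQR of the two tables (zero-IQR columns pass through
  unscaled). Robust location/scale keeps a handful of extreme branches
  from dominating the projection geometry.
* **Directions are fixed per run**, not redrawn per optimisation
  iteration: the objective must be a pure function of the parameter
  vector for the genetic algorithm to converge.
* **Empty tables** (e.g. a young simulated tree with no order-4 branches
  when `B^{2,3,4}` is requested) score the maximal distance 1. This
  steers the optimiser toward parameter regions that produce the missing
  orders instead of silently dropping the pair.
* The default is 1000 lines; distance work is linear in lines and table
  pairs and `n log n` in samples (dominated by the per-line sort), which
  the test suite asserts as operation counts rather than wall-clock.

Classical metrics provide the traditional reference frame: height (the
highest cylinder endpoint), girth (diameter of the ground segment —
breast-height diameter is undefined for shrubby, multi-stemmed forms),
and crown spread by the spoke method (36 spokes at 10° separation from
the root's XY position; each spoke is the maximal horizontal distance of
any cylinder endpoint in its half-open sector, empty sectors count 0;
the spread is twice the mean spoke). Relative errors `d_h, d_g, d_c`
divide by the reference tree's value, so girth errors above 100% are
representable — and do occur, since girth spans centimetres on trees that
span metres.

## The growth simulator

The simulator is a self-organizing tree model: architecture emerges from
competition for light rather than from a prescribed recursive plan.
Per iteration:

1. **Shadow pass.** Every bud and segment tip deposits shadow into a voxel
   grid: layer `q` of an inverted pyramid below the point (a
   `(2q+1)×(2q+1)` square, `q` layers down) gains `a·b^{−q}`, for
   `q = 0..depth`. The implementation batches this by tabulating points
   per voxel and box-summing per slice with summed-area tables, which is
   algebraically identical to summing per-point pyramids.
2. **Light exposure.** A bud in a voxel with accumulated shadow `s`
   receives `Q = max(C − k·(s − a), 0) · g(z)`, where the `−a` removes the
   bud's own deposit, `k` is the shading sensitivity and `g(z)` an
   optional linear vertical gradient (uniform light, `g ≡ 1`, by
   default).
3. **Resource allocation.** Exposures are summed basipetally to the root;
   the total is converted to resource `v = α_R · ΣQ` and redistributed
   acropetally. At each node the continuing direction receives
   `v·λQ_m/(λQ_m + (1−λ)ΣQ_l)` and laterals share the remainder in
   proportion to their light (extended Borchert–Honda). `λ = 1` is full
   apical dominance, `λ = 0` full lateral dominance; resource is conserved
   whenever any light reaches the node.
4. **Growth.** Each bud converts resource `v` into `floor(v)` metamers of
   fixed length 0.2 m. Growth directions take per-metamer stochastic
   deflection (normal or uniform noise), a tropism pull, and for laterals
   a branching angle (mean ± spread) at an azimuth advanced by the
   phyllotactic divergence angle. Each metamer bears one lateral bud
   (subject to the order cap); laterals may be dormant for a configurable
   delay and flush with a bud-break probability. Growth is clipped to the
   arena.

After the final iteration, radii are assigned by the pipe model
(`tip_radius` at leaves, `r_p = (Σ r_c^e)^{1/e}` inward) and orders are
extracted with the thickest-branch rule — for strongly apically dominant
forms this coincides with the analytic lateral/extension bookkeeping, and
for weakly dominant (shrubby) forms it is the same convention applied to
QSMs, which is what makes simulated and measured tables comparable.

**Parameter inventory.** The model has 27 parameters: 23 grouped —
group I growth/pipe (resource coefficient, pipe exponent, tip radius, max
order, iteration count), group II environment (shading sensitivity, light
gradient, tropism strength/azimuth/elevation), group III apical dominance
(λ, bud-break probability, lateral delay), group IV shadow (a, b, base
exposure C, pyramid depth), group V angular (branching angle mean and
spread, divergence angle and spread, heading noise, noise kind) — plus 4
fixed constants (segment length 0.2 m, voxel size 0.2 m, arena size 12 m,
arena origin at the centre of the floor). The literature on
self-organizing models treats the shadow kernel and allocation weighting
as tunable constants; the defaults here (`a = 0.1`, `b = 2`, `depth = 4`,
`C = 1`) are conventional mid-range values, and all of them are exposed
as ordinary parameters so the optimiser may move them.

**Reproducibility.** Each growth iteration runs on its own derived RNG
substream, and buds are processed in deterministic storage order, so
`simulate_tree(params, seed)` is bit-stable across runs — the contract
that optimisation requires (the objective must return the same value for
the same parameter vector). Default sizes: with the 12 m arena and 20
iterations a tree has some hundreds to a couple of thousand cylinders;
the examples and tests mostly use a 6 m arena and 7–12 iterations
(roughly 40–150 cylinders), which exercises every code path at a size
where a full genetic-algorithm recovery runs in minutes.

## Inverse fitting

The objective simulates at parameter vector `v` (fixed seed), extracts
the configured table pairs (e.g. `S^{0,1}` and `B^{2,3,4}`, the merged
sets that capture low- and high-order structure at once), and returns the
mean `D_S` against the target tables. Simulation failure or a missing
order scores 1.

The genetic algorithm is self-contained: tournament selection of size 3,
intermediate crossover at rate 0.8, uniform-reset mutation at rate 0.15,
integer-aware sampling and mutation for integer parameters, one elite
individual per generation, and stopping after a stall window (default 10
generations without improvement) or a generation cap. Two kinds of ranges
control the search: global bounds (never exceeded) and initial ranges
(from which the first population is drawn). Sequential refinement —
re-centring initial ranges on the previous best while keeping the global
bounds — is provided by `recenter_specs()`. The distance landscape along
any single parameter is rugged and replicate-dependent
(`distance_profile()` makes such scans directly), which is why a
population-based stochastic optimiser is used rather than a smooth-descent
method.

## Synthetic targets and what the tests show

The fixture generator provides (i) a deterministic fractal tree with
closed-form height, girth, crown spread, per-order branch counts `2^w`
and exactly pipe-consistent radii; (ii) a simulated self-target returned
with its generating parameters, for recovery experiments where the true
optimum (distance exactly 0 at the generating parameters and seed) is
known; and (iii) a corrupter that jitters radii and axis directions while
re-chaining the geometry, emulating measurement and reconstruction noise
at a chosen level.

These fixtures emulate the *scale and structure* of QSM data (thousands
of cylinders are reachable via depth; orders 0–4; pipe-consistent radii)
but not its failure modes: no partial occlusion, no over-segmentation, no
systematic lean from wind or neighbours, and the fractal's feature
distributions are atomic (many identical values) where real ones are
spread. Passing tests therefore demonstrate the correctness of the
machinery — distances, extraction, simulation, optimisation — not that
any particular real species is well fitted; fitting a real QSM remains an
empirical exercise with the user's own data.

## Known limitations

* The thickest-branch rule is an approximation to full topological
  reconstruction; on near-tie junctions of real QSMs it can flip branch
  identities.
* The simulator omits leaves, seasonal phenology and directional
  environment (prevailing wind, neighbour shading), so systematic crown
  asymmetries in a target cannot be reproduced, only averaged over.
* Fits are identified only up to rotation about the vertical axis, and
  the fixed 0.2 m segment length bounds from below the fineness of
  radius/length distributions the model can match.
* `D_S` compares distributions, not geometry: two trees with identical
  feature tables but different spatial arrangements are equidistant. That
  is by design — it is what makes clones *clones* rather than copies.
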