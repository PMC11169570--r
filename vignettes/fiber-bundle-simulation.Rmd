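---
title: "Simulating white-matter fiber bundles and benchmarking fiber clustering"
author: "fibersim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating white-matter fiber bundles and benchmarking fiber clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibersim)
```

## The problem

Fiber clustering algorithms group diffusion-MRI tractography streamlines
into anatomically coherent bundles, but real tractography has no ground
truth: nobody knows which cluster each streamline "really" belongs to.
`fibersim` addresses this by simulating whole-brain tractography datasets
whose per-fiber bundle membership is known by construction, so that a
clustering can be scored objectively.

## The tubular bundle model

A bundle is generated from three inputs: a **centroid** (a 21-point 3D
polyline describing the trajectory), **five radii** and a **fiber count**.
Five circular cross-sections are erected perpendicular to the centroid at
point indexes 0, 3, 10, 17 and 20 — the two ends, two intermediate
stations and the center, the points that best summarize a tubular bundle's
shape. Each circle is realized as eight peripheral points: an initial
point at distance $r_i$ from the center $P_{c_i}$, rotated seven times by
multiples of 45° about the local unit tangent $\vec{U_{t_i}}$, delimiting
eight 45° circular sectors. The rotation uses the axis–angle (Rodrigues)
matrix

$$R = \cos\theta\, I + \sin\theta\, [\vec{u}]_\times +
      (1-\cos\theta)\, \vec{u}\vec{u}^{\top},$$

written entrywise in `rotation_matrix()`, and verified in the tests
against an independent quaternion construction to $10^{-10}$.

Tangents come from an interpolating cubic spline per coordinate over a
chord-length parametrization of the centroid, differentiated analytically
(`centroid_tangents()`). Chord length rather than uniform parametrization
was chosen because the 21 centroid points need not be equispaced after
alignment and averaging; for equispaced points the two coincide.

**Circle alignment.** So that sector $k$ of one section corresponds to
sector $k$ of the next (and fibers do not twist around the tube), the
radial direction of the first circle — a deterministic perpendicular of
its tangent, so every run is reproducible — is propagated along the tube:
each subsequent circle projects the previous circle's radial direction
onto its own plane, a discrete parallel transport. On a straight centroid
this makes all sections share identical sector directions exactly.

## Fiber generation

For each fiber, a sector 0–7 is drawn uniformly, and one control point is
sampled **area-uniformly** over that sector's disc wedge in each of the
five sections (radius $r\sqrt{u}$, angle uniform in the wedge; the mean
radial distance of such samples is $\tfrac{2}{3}r$, which the tests use as
an oracle). Keeping all five control points in the same angular lane is
what lets fibers run the length of the tube without crossing through the
core.

The five control points define a **fourth-order spline with clamped
ends** — in Bernstein form, a degree-4 Bézier curve. The curve starts and
ends exactly at the first and last control points and *approximates* the
curve between the inner ones, never leaving their convex hull. This
containment property is the reason this reading was chosen over a degree-4
*interpolating* polynomial: the interpolant overshoots the tube radius by
20–30% on realistic control nets (measured on straight cylinders under
both chord-length and uniform parametrizations), whereas the Bézier curve
keeps every fiber inside the tube by construction. The curve is then
resampled to 21 approximately equidistant points along its arc length
(dense evaluation at 200 parameters, linear interpolation at equal
arc-length steps; consecutive spacings agree to well under 2% for
tube-like control nets).

Optional **Gaussian end noise** adds an i.i.d. per-coordinate normal
displacement (mean 0 by default, standard deviation $\sigma$) to the five
points at each fiber end (0-based indexes 0–4 and 16–20), emulating the
dispersed terminations of real bundles. The perturbation is isotropic 3D
with the stated per-coordinate $\sigma$; the dimensionality convention is
ours, and $\sigma$ is recovered from the simulated displacements within
5% at $n = 10{,}000$ in the tests.

## Whole-brain ground truth

`build_dataset()` simulates one bundle per centroid with per-bundle
parameters drawn from calibrated ranges: end radii $r_1, r_5 \in [8, 10]$
mm, intermediate $r_2, r_4 \in [6, 8]$ mm each constrained below its end
radius, central $r_3 \in [5, 7]$ mm below both intermediate radii (so
tubes pinch smoothly toward the middle), 50–300 fibers per bundle and
$\sigma \in [2.5, 3.5]$ mm. Draws over bounded ranges follow a truncated
normal centred at the range midpoint with $sd = \text{range}/4$
(redraw-until-in-range), honouring both the stated normality of the
selections and the hard bounds; a uniform alternative is available via
`dataset_spec(distribution = "uniform")`. Ordering constraints are
enforced by capped redraws.

Centroids can be sampled from a real tractography with
`select_centroids()` (length $> 50$ mm, pairwise maximum-Euclidean flip
distance $\ge 10$ mm) or generated synthetically with
`generate_synthetic_centroids()`: random quadratic arcs inside an
ellipsoid of adult-brain dimensions (semi-axes 70 × 85 × 60 mm), endpoint
separations 60–150 mm, passed through the same two filters. The synthetic
generator reproduces the *statistical* structure such centroids need
(length, smoothness, spatial spread, pairwise separation) but not the
anatomy of real tracts — no sheet-like geometries, no anatomically
constrained trajectories — so tests passing on synthetic data demonstrate
algorithmic correctness, not anatomical fidelity.

**Per-bundle seeding.** Each bundle's RNG stream is derived from the
dataset seed and a hash of its centroid's coordinates, not from its list
position: permuting the centroid input order permutes bundle labels but
leaves every bundle's geometry bit-identical, which the tests assert.

**Crossing registry.** Two bundles *cross* when they contain fibers
closer than 10 mm in the flip-max distance. Detection prefilters pairs
with the metric bound $\min_{f,g} d(f,g) \ge d(c_A, c_B) - R_A - R_B$
(valid because the flip-max distance is a metric) and checks survivors
exactly; the registry equals a brute-force all-pairs scan in the tests.

## Similarity and evaluation metrics

The fiber distance is the **maximum-Euclidean flip distance**

$$d_{ME}(A,B) = \min\Big(\max_i \|a_i - b_i\|,\;
                         \max_i \|a_i - b_{N_p - i}\|\Big),$$

the flip term covering the two possible storage orientations. On top of
it: the **inter-bundle distance** (mean ± sd of pooled nearest-fiber
distances, symmetrized over both directions, since the definition is
directionless) and the **intersection percentage** (share of *reference*
bundle fibers having a counterpart within 10 mm; the reference is the
ground-truth/atlas bundle because the question asked is how much of the
original bundle the simulation reproduces — a symmetric variant is a
flag).

Clusterings are scored with the Overlap Score
$OS(C_p, C_g) = |C_p \cap C_g|^2 / (|C_p||C_g|)$. A predicted cluster is
a true positive when it matches a ground-truth cluster with
$OS \ge 0.8$; matching is one-to-one, greedy in descending OS (at the 0.8
threshold two predicted clusters cannot both clear it against the same
ground-truth cluster, so greedy and exact matching coincide there; the
greedy rule matters only for exploratory lower thresholds). From
TP/FP/FN follow Precision, Recall and F-measure; from the full
contingency table the clustering-wise Sensitivity, PPV and their
geometric mean (Accuracy); the **Maximum Matching Ratio** sums the OS of
TP matches over the number of ground-truth clusters. The MMR is also
describable as a maximum-weight bipartite matching; both variants are
implemented (`mmr()`, `mmr_exact()`), the TP-sum form being the default
because it is the operational definition the metric suite is built
around. Fibers a clusterer marks as noise count toward no predicted
cluster and reduce only the sensitivity numerator. Zero denominators in
Precision/Recall return 0 with a warning.

The built-in **QuickBundles baseline** is the classic greedy single-pass
clusterer with the MDF distance (mean point-wise distance, minimized over
flip) on 12-point resampled fibers, with running-mean centroids updated
from flip-aligned incoming fibers. It is verified against an
independently coded per-pair reference implementation. External
clusterers plug in as functions (or via the CLI adapter: bundles file in,
one label per line out). The **permutation harness** applies
Fisher–Yates shuffles to the input order and reports metric means and
standard deviations; for an order-invariant clusterer the spread is
exactly zero.

## Numerical choices and degenerate inputs

* Geometric identities (coplanarity, radius, 45° spacing) are asserted at
  $10^{-6}$ mm; rotation exactness at $10^{-10}$.
* A reference direction parallel to a section tangent falls back to the
  deterministic perpendicular (with a message); coincident spline control
  points, zero-extent centroids, empty bundles and all-zero contingency
  tables are errors.
* Recovered radii under 0.1 mm are clamped before re-simulation, since a
  zero radius cannot seed the tubular model.
* Orientation alignment compares the *sum* of both endpoint-pair
  distances (direct vs crossed) and flips only when strictly larger, so
  ties leave fibers unchanged.
* File I/O is little-endian single precision; coordinates round-trip
  bit-exactly once quantized, and identical inputs produce byte-identical
  files.

## Problem sizes used in tests

The test-suite and acceptance-script scales were chosen to exercise every
code path at desk scale: cylinder diagnostics with 500 fibers, noise
recovery from 10,000 displacement draws, 10,000 parameter draws for the
range constraints, brute-force oracle comparisons on 20+ random
instances, and a 20-bundle whole-brain benchmark. For that benchmark the
ellipsoid semi-axes are scaled by $(20/100)^{1/3}$ so that its *bundle
density* — and with it the crossing pressure that makes clustering hard —
matches a 100-bundle full-brain dataset; at full-brain volume 20 bundles
would be unrealistically sparse and every threshold would cluster
perfectly. The benchmark reproduces the expected qualitative pattern:
cluster counts fall monotonically with the distance threshold, the best
F-measure sits at an intermediate threshold (12–15 mm), and permutation
standard deviations are small.

## Known limitations

* **Curvature flattening.** The approximating spline sags toward the
  control-polygon chords, so strongly curved bundles are simulated
  slightly inside their nominal trajectory and the recovered centroid of
  a curved bundle is biased inward (about 3 mm for an 80 mm arc of 60 mm
  radius, shrinking as curvature decreases; straight bundles recover to
  0.1 mm RMS). The simulated bundle is internally coherent — fibers
  follow one common, slightly flattened trajectory — which is what
  matters for clustering ground truth.
* **Radius shrinkage.** Because control points are area-uniform in their
  discs, the mean fiber-to-centroid distance at a section is about
  $\tfrac{2}{3}$ of the generating radius; `estimate_radii()` measures
  that mean, so profile-and-resimulate loops contract bundles unless the
  bias is corrected by the caller.
* Only tubular bundles: sheet-like tracts (corpus callosum, short
  cingulum) cannot be represented by a single linear centroid with
  circular sections.
* No kissing/fanning configurations, fiber-density fields, or diffusion
  signal synthesis.
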