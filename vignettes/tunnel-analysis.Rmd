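---
title: "Tunnel identification and clustering: model, parameters, design"
author: "tunnelscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tunnel identification and clustering: model, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the geometric model behind tunnelscape, the
parameters a user is expected to tune, the numerical choices the
implementation makes where the mathematics leaves freedom, and what the
synthetic fixtures do and do not establish about real data.

## The model

### Equal-radius ball representation (RIS)

Ordinary (point-site) Voronoi diagrams are far better behaved than
additively weighted ones, but protein atoms have different van der Waals
radii. The package therefore approximates every atom *from the inside* by
balls of one common radius `r_min`, the smallest vdw radius present in the
snapshot. An atom of radius `R > r_min` is represented by one ball at the
atom center plus up to `ballsPerAtom − 1` balls placed at distance
`R − r_min` from the center along a fixed near-uniform (golden-angle
spiral) direction set, which guarantees every ball lies inside the atom.
Consequently the RIS surface never rises above the vdw surface: pathway
radii can be **overestimated but never underestimated**. The worst-case
overestimation is computable from the arrangement — for each atom it is

    min( R − r_min,  sqrt(R² + d² − 2Rd·cosθ) − r_min ),   d = R − r_min

where θ is the covering angle of the direction set (evaluated numerically
once per set size); the maximum over atoms, plus the center-perturbation
allowance below, is reported as the RIS `errorBound` and echoed into every
run manifest. The bound applies to points outside the vdw volume, which is
where pathway balls live. Note the corollary: an edge whose *true* width is
just below the probe radius may survive the probe filter when the
overestimation bridges the difference, so a reported pathway can be narrower
than `r_B` by at most `errorBound` — the acceptance suite checks exactly
this containment on mixed-radius fixtures.

To avoid degenerate (co-spherical) site configurations, every ball center is
perturbed by a deterministic pseudorandom offset below 0.001 Å per
coordinate. The perturbation comes from a dedicated linear congruential
generator seeded by the user-visible `seed`, so it never disturbs R's global
RNG stream and is reproducible bit for bit. If the triangulation still
reports a degeneracy, the pipeline rebuilds the RIS with `seed + 1`, up to
three times, before failing.

### Voronoi graph

The Delaunay triangulation of the ball centers (computed by an incremental
Bowyer–Watson insertion implemented in C++) yields one Voronoi vertex per
tetrahedron — its circumcenter — and one edge per interior face. Because all
balls share one radius, every point of a Voronoi edge has the three defining
face sites as its nearest sites, so the minimum clearance along an edge has
the closed form `min distance from a defining site to the segment − r_min`;
tests validate this against dense sampling of the global clearance field.

Unbounded exterior Voronoi cells are made traversable by surrounding the
structure with a shell of far dummy sites (42 golden-angle directions at the
structure's bounding-sphere radius plus `shellMargin`, default 30 Å). This
is purely an implementation device: clearances and costs of dummy-adjacent
elements are computed from the global clearance field, and the test suite
checks that identified tunnels are insensitive to the shell radius.
Vertex clearance may legitimately be negative inside overlapping bonded
atoms; such regions are removed by the probe filter rather than forbidden by
the data structure.

### Cost, search, trimming

A corridor of length L and clearance profile r(l) costs
`∫₀ᴸ dl / r(l)ⁿ`, with r(l) clamped to `[0.1 Å, maxRadius]`. The wording
"at least 8 trapezoids, grid at most 0.1 Å" is internally tense for short
edges; the implementation uses `T = max(8, ceil(L / 0.1))` trapezoids,
which satisfies both readings. Throughput is `e^(−cost)`, a (0, 1] score
monotone in cost.

Identification in one snapshot proceeds as:

1. remove edges with minimum clearance below the probe radius `r_B`;
2. flood-fill from the exterior over edges traversable by the shell probe
   `r_S` to label **bulk solvent vertices**, each receiving a bulk ball of
   maximal radius not intersecting the RIS;
3. from every bulk ball (center A, radius r), flood-fill with the probe
   `r_B` confined to the sphere of radius `r + d_s` around A to label
   **surface vertices**; boundary subsets follow from adjacency;
4. optimize the starting vertex from the user's selection by a four-stage
   cascade (closest within `d_max` with clearance ≥ `r_min`; else maximal
   clearance within `d_max`; else both again with 3 Å; else globally
   closest);
5. Dijkstra from the starting vertex to every reachable surface boundary
   vertex, **excluding bulk vertices** — allowing step 1 to roam the bulk
   would manufacture wrap-around "tunnels" hugging the outer surface, and
   the dedicated continuation step would be pointless;
6. prolong each path by its single cheapest continuation through
   surface ∪ bulk vertices to a bulk boundary vertex;
7. place balls along the axis every `ballSpacing` Å with maximal
   non-colliding radii, and trim balls from the *end* of the path until one
   with radius ≤ `r_S` is reached (the start is never trimmed);
8. remove redundant pathways greedily in ascending cost order, discarding
   pathways within `redundancyThreshold` of a kept one.

Pathway cost is re-integrated along the resampled, trimmed axis with the
same quadrature, so the reported cost, throughput, profile and bottleneck
are all statements about the same polyline. Radii are clamped to
`maxRadius` only *inside* the cost integral; reported profiles and
bottlenecks use the unclamped maximal ball radii.

### Descriptors, distance, clustering

The frame origin S is the center of gravity of the per-snapshot starting
vertices. Direction points accumulate pathway extreme points processed in
ascending cost order (so the construction is order-canonical): a new extreme
point either founds a direction point or updates the nearest one (within
`mergeAngle`). The update keeps a **running weighted mean** of straight
lengths, `(|SX| + w·|SY|)/(w + 1)`; a literal sum would grow without bound
and contradict the averaging intent. The direction vector of an existing
point is kept fixed; only its length and weight change.

For each pathway, `d_end` is the weight-averaged straight length over the
direction points within `smoothness` of its extreme direction (the nearest
point if none qualifies). The interval `[z_start, d_end − z_end)` is split
into N equal bins; G_i is the centroid of the axis points whose distance
from S falls in bin i. Empty bins are filled by linear interpolation between
neighbouring non-empty points (ends extrapolated from the nearest segment):
descriptors must have exactly N points for the k-NN features to align.

The pathway distance is the arithmetic mean of `w(xᵢ)·|G_Ai G_Bi|` at bin
midpoints `xᵢ = (i − 0.5)/N`, with the linear weight solved from
`w(0.5) = 1`, `w(1)/w(0) = q`. The equivalent K-point form
(`K_i = S + w(xᵢ)(G_i − S)`) is implemented as a cross-check; both agree to
10⁻⁹ in the tests. With `q = 1` the distance is a pseudo-metric; for
`q ≠ 1` the triangle inequality is not asserted.

Average-link agglomeration is implemented directly (Lance–Williams update,
ties to the lowest indices) and stores the full merge tree, so re-cutting at
a new threshold costs nothing; `stats::hclust` and a naive from-scratch
agglomerator serve as independent oracles in the tests. The large-set path
clusters a seeded random sample exactly, keeps the `topN` highest-priority
clusters as classes plus one "other" class, and assigns remaining pathways
with an in-package k-NN whose ties are deterministic (lowest class, then
lowest training index); pathways classified as "other" stay in that class
and are excluded from top-N statistics.

## Parameters

| parameter | default | unit | meaning |
|---|---|---|---|
| `costExponent` (n) | 2 | — | width/length balance of the cost integral; 0 prices pure length; capped at 100 |
| `maxRadius` | 5 | Å | clearance cap inside the cost integral |
| `probeRadius` (r_B) | 0.9 | Å | minimal pathway width; edges narrower are removed |
| `shellProbeRadius` (r_S) | 3 | Å | exterior/bulk accessibility probe; also the end-trimming radius |
| `shellDepth` (d_s) | 4 | Å | depth of the surface layer below each bulk ball |
| `startMaxDist` (d_max) | 3 | Å | starting-vertex search radius |
| `startMinClearance` (r_min) | 2 | Å | required starting-vertex clearance |
| `ballSpacing` | 0.5 | Å | axis sampling interval; bottleneck resolution is ± spacing/2 |
| `ballsPerAtom` | 12 | — | RIS balls per oversized atom; more balls shrink `errorBound` |
| `threshold` | 3.5 | — | average-link tree cut height |
| `redundancyThreshold` | = threshold | — | per-snapshot duplicate removal distance |
| `nPoints` (N) | 20 | — | descriptor points per pathway |
| `q` | 1 | — | end/start weighting of the pathway distance |
| `zStart`, `zEnd` | 0 | Å | ignored start/end sections of the descriptors |
| `mergeAngle`, `smoothness` | 20 | ° | direction-point merge and d_end-averaging angles |
| `openRadius` | 1.4 | Å | water-probe convention for "open tunnel" counting |

The probe radius 0.9 Å and thresholds 3.5/4.3 are the values used in
published haloalkane dehalogenase analyses; descriptor defaults (N = 20,
q = 1, 20° angles) are this package's own choices, exposed for tuning. The
defaults `d_max = 3 Å` and `r_min = 2 Å` make the starting-point
optimization tolerant of selections that sit against or slightly inside the
atom packing while still refusing to jump out of the target cavity.

## The synthetic fixtures

`makeShellEnsemble()` builds a hollow sphere of overlapping carbon-like
pseudo-atoms (layered golden-angle lattices, tangential spacing 2.0 Å,
radial step 1.4 Å — tight enough that no spurious probe-sized passage exists
through the wall, which the sealed-shell test verifies). Channels are
drilled along chosen directions, and a ring of gate atoms at mid-shell depth
sets the channel's minimum free radius *exactly* per frame, so bottleneck
values and gating schedules are known by construction. With a single
pseudo-atom radius the RIS is exact up to the perturbation allowance,
isolating search/clustering behaviour from approximation error; the
mixed-radius variant (alternating C/N) exercises the RIS bound itself.

What the fixtures emulate: buried cavities, probe-tight walls, multiple
channels at controlled angles, per-frame gating, exact ground truth. What
they do not: conformational backbone motion, side-chain packing
heterogeneity, solvent and ions, non-spherical atoms' chemistry, or the
scale of real trajectories (thousands of snapshots, tens of thousands of
pathways). Passing fixture tests therefore demonstrates correctness of the
geometry, search, clustering and reporting machinery under known truth — not
biological validity of any particular parameter choice on a given protein.
Test and acceptance runs use 1–50 frame ensembles of ~450 pseudo-atoms,
sizes chosen so the whole suite re-runs in minutes on one core.

## Numerical choices and degenerate inputs

- Quadrature: trapezoidal, `T = max(8, ceil(L/0.1))`; a constant-clearance
  corridor is integrated exactly, which the closed-form tests exploit.
- Tie-breaks are deterministic everywhere: lowest vertex index in the
  starting-vertex cascade and step-2 target choice, lowest pair indices in
  agglomeration, earliest pathway index in redundancy removal, lowest
  class/training index in k-NN. Two runs with the same seed produce
  byte-identical CSV outputs; the worker count only distributes snapshots
  and never changes results.
- Coplanar or otherwise degenerate site sets produce no tetrahedra among the
  ball sites and raise an error advising a different perturbation seed; the
  pipeline retries `seed + 1 … seed + 3` automatically.
- Empty descriptor bins are interpolated; a pathway with a single non-empty
  bin replicates it, and one with none is an error.
- `d_end ≤ z_start + z_end` is a parameter error, not a silent clamp.
- Pathways whose step-1 endpoint has no continuation to a bulk boundary
  vertex are dropped; snapshots without reachable surface boundary vertices
  legitimately yield an empty pathway list (e.g. the sealed shell).

## Limitations

- Geometry only: no energetics, electrostatics or ligand-specific transport;
  throughput is a geometric importance score, not a rate.
- Input must be pre-aligned with consistent numbering; no superposition, no
  protonation. Results depend on the vdw radii table (Bondi 1964 default)
  and on hydrogens being present or absent.
- The curvature descriptor is simply axis length over straight end-to-end
  distance, and is labelled as such in the outputs.
- Numerical identity with other tunnel-analysis programs is not claimed:
  ball-placement geometry, radii tables and several descriptor constants
  (d_end averaging, distance aggregation, direction-point updates) are
  documented package choices where the published prose leaves the exact
  formula open.
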