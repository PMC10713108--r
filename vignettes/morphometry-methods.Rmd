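---
title: "Mesh-based morphometry of segmented volumes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mesh-based morphometry of segmented volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphmesh)
```

`morphmesh` measures the 3D shape of segmented biological objects. This
vignette is the package's own account of the methods: what each procedure
assumes, which parameters matter and why their defaults are what they are,
what the synthetic fixtures do and do not demonstrate, and where the design
was genuinely open.

## Coordinate and unit conventions

Label volumes are indexed `(z, y, x)` — slice, row, column — with a per-axis
physical voxel size `spacing` (same order) and a physical `origin` for the
centre of voxel `(0, 0, 0)` (voxel-centre convention). Meshes, center lines
and all reported coordinates live in a right-handed `(x, y, z)` frame in the
input's length unit; by convention that unit is µm, and the package never
rescales. Areas and volumes are therefore µm² and µm³ whenever inputs are µm.

## Surface extraction

Each label's binary mask is padded by one background voxel on every face —
so objects touching the stack border still produce closed surfaces — and an
iso-surface is extracted at level 0.5. The extractor is a marching-cubes
variant that splits every grid cell into the six Freudenthal tetrahedra
sharing the cell's main diagonal. Because that decomposition is translation
invariant, the face diagonals of neighbouring cells coincide and the output
is watertight for *every* input mask; the classical 256-case cube table, by
contrast, can crack at ambiguous saddle configurations. Crossing vertices
sit at segment midpoints between an inside and an outside grid point, which
reproduces a flat axis-aligned boundary exactly at the half-voxel position
and keeps the surface estimate unbiased to first order. On a discrete ball
of radius 20 voxels the meshed volume is within 0.5% of 4/3·πr³ (tested at
radii 5, 10, 20 with monotonically shrinking error).

Two consequences users should know. First, tetrahedral decomposition emits
roughly twice as many triangles as cube-table marching cubes; for
measurement (rather than rendering) this is irrelevant, and no smoothing or
decimation is applied by default so area/volume results are deterministic.
Second, the *area* of a marching-cubes surface of a staircase mask
overestimates the smooth-object area (by ~27% for a sphere); this is a
well-known property of all voxel iso-surfaces at this fidelity, so
resolution-robust area comparisons should be made between meshes of similar
voxel size.

## Area, volume, orientation

Surface area is the exact triangle-area sum; enclosed volume is the
divergence-theorem sum Σ a·(b×c)/6, meaningful only for closed, consistently
oriented surfaces. The watertight test requires every undirected edge to be
shared by exactly two faces traversing it in opposite directions. On import,
winding is made consistent by breadth-first propagation across shared edges
and each closed component is flipped, if needed, so its signed volume is
non-negative. For open meshes the volume of a "segment" is biologically
undefined, so `enclosed_volume()` refuses with the boundary-edge count;
`force = TRUE` returns the absolute raw integral for power users, clearly
warned. Degenerate faces (repeated indices or zero area) are dropped at load
with a logged count — marching-cubes output can contain slivers, and
dropping keeps the integrals well defined.

## Cross-sections

A center line is either an explicit polyline or the dominant principal axis
of the mesh's vertex cloud, clipped to the projection extent. If the top two
covariance eigenvalues differ by less than 10% the object has no meaningful
elongation; the axis is still returned but flagged low-anisotropy, since any
direction would be nearly as good. Planes sit at uniform arc-length stations
with the two end stations inset by half a step — without the inset the end
planes would sit exactly at polyline endpoints where the tangent is
one-sided. At interior polyline vertices the normal is the mean of the
adjacent segment directions.

Each plane cut computes one crossing point per cut mesh edge (shared edges
are computed once, so loop chaining is exact rather than
tolerance-dependent) and chains triangle segments into closed loops;
vertices lying exactly on the plane are first nudged by 10⁻⁹ of the bounding
box along the normal, which removes the triangle-in-plane degeneracy without
measurable geometric effect. Loops are classified outer/hole by containment
parity and wound CCW/CW respectively. Open chains — possible only when the
plane cuts a mesh boundary — are discarded from the properties and counted
in a warning.

The nine per-section properties follow the conventions of standard 2D
region-properties tools so values can be compared against image-based
pipelines:

* area = outer areas − hole areas (shoelace), perimeter = **all** ring
  boundaries including holes (a section with a lumen has more boundary);
* convex hull over all ring vertices gives convex area and convex perimeter;
  convexity in area = A/A_hull, convexity in perimeter = P_hull/P — both
  definitions keep the ratio in (0, 1];
* equivalent (Heywood) diameter √(4A/π);
* axis lengths are those of the ellipse with the region's normalized second
  central moments (4·√eigenvalue), computed from exact polygon moment
  integrals with holes subtracting naturally — not a bounding-box
  convention. The test suite cross-checks them against an independent
  2048² scanline-rasterization moment oracle to within 1%.

Whether hole rings should count toward the perimeter, and whether axis
lengths should come from moments or a minimum bounding rectangle, are
genuinely open conventions; the choices above are documented precisely so
users can reconcile results with other tools.

## Skeletonization

The skeletonizer is a TEASAR-family algorithm on the 26-connected voxel
graph, edge weights equal to physical centre distances, fully
anisotropy-aware (no resampling):

1. **DBF** — Euclidean distance from every foreground voxel to the nearest
   background voxel (stack borders count as background), computed by a
   separable lower-envelope distance transform with per-axis spacing. The
   DBF doubles as the local radius estimate written to SWC.
2. **Root** — two-pass farthest-point search from the lowest-index
   foreground voxel, then the root is *re-centred*: snapped to the
   highest-DBF voxel within a local ball of radius `DBF_max + const`. Tip
   re-centring is the step that keeps path endpoints on the medial axis
   instead of on surface corners (the geodesically farthest voxel of a tube
   is a rim voxel, ~r off-axis).
3. **Path tracing** — repeatedly, the farthest still-uncovered voxel (ties
   to the lowest linear index) is re-centred and connected to the root by a
   shortest path in a penalized metric: each voxel adds
   `5000 · max(spacing) · (1 − DBF/DBF_max)^p` with exponent `p = 4`.
   The penalty scale dominates any path-length difference, so paths follow
   the DBF ridge; the exponent sharpens the ridge preference. Traced edges
   become nearly free so later paths reuse the existing skeleton and branch
   off it. After each path, all voxels within `scale · DBF + const` of its
   nodes are marked covered (`scale = 2`, `const` = one mean voxel length by
   default; larger `scale` coarsens the skeleton and can only reduce the
   node count).
4. **Tree + pruning** — the union of traced paths is reduced to a tree
   (minimum spanning tree on physical lengths, a no-op unless path reuse
   created a cycle), and leaf branches shorter than
   `max(2 · DBF(junction), const)` are pruned: such spurs are voxelization
   whiskers, not anatomy. All tie-breaks use the lowest linear voxel index,
   so results are bit-reproducible.

On the straight-tube fixture (r = 4, 60 slices) every node lies exactly on
the axis and the arc length is 53 of 59 voxel units — tips re-centre roughly
one radius inward from each end, the expected cost of medial tips. A ball
has no elongation and collapses to a single node. The algorithm follows the
published TEASAR/Kimimaro design but is an independent implementation; exact
output parity with any particular library is a non-goal, and the parameters
above are this package's own documented defaults.

`voxelize()` bridges meshes to the skeletonizer: a voxel is foreground iff
its centre is inside the watertight mesh by ray-crossing parity along +x,
with ray coordinates nudged off the lattice so rays never graze edges.

## Distances

Surface distance runs Dijkstra on the mesh's vertex–edge graph with
Euclidean edge weights. This is deliberately *not* an exact polyhedral
geodesic: the graph distance is an upper bound that depends on mesh
resolution (≈ +2–8% versus the great-circle arc on a subdivision-4
icosphere), but it is exactly reproducible, cheap, and matches what
mesh-based tools commonly report. The test suite verifies it against an
exhaustive relaxation oracle to 10⁻¹², which a floating-point-identical
alternative implementation must satisfy. Interactive point picking is
replaced by nearest-vertex snapping with the snap distance reported, so a
bad pick is visible in the output.

## Angular distribution

The spread of an object around a reference point is summarized by the mean
and population standard deviation of the angles θ ∈ [0, π] subtended at the
reference between the anchor direction (fixed point − reference) and sampled
surface points. The fixed anchor defaults to the area-weighted surface
centroid — deterministic and landmark-free — and can be overridden when a
biological landmark (e.g. a nucleus centre) is more meaningful. Sampling is
uniform by surface area (triangle selection proportional to area, uniform
barycentric point), making the statistic independent of mesh resolution;
a vertex-sampling mode exists for parity with vertex-cloud tools. Defaults:
10 000 samples, seed 0; the Monte-Carlo standard error of the mean is
σ/√n ≈ 0.0004 rad for a radius-2 object seen from 10 units. A larger mean
indicates a broader spread; interpreting the standard deviation (e.g. as
uniformity) is left to the analyst, since it is a summary, not a model.

## The synthetic fixtures, and what passing tests show

All tests run on generated shapes with closed-form properties: spheres and
cubes pin area/volume, cylinders and tori pin sectioning (including
multi-loop and annular topologies), tubes and Y-junctions pin skeleton
geometry and topology, small shells pin the angular statistic, and
multi-label ball volumes pin label handling. The generators emulate the
*geometry* of segmented microscopy objects — anisotropic voxels, border
contact, multiple labels, branching — but not its *pathologies*: no
segmentation noise, no holes in masks, no touching objects sharing a
boundary, no non-manifold meshes from other software. Passing tests
therefore demonstrate correctness of the geometric computations, not
robustness to upstream segmentation errors; meshes from third-party
pipelines should be checked with `is_watertight()` and `measure()`'s note
column before volumes are trusted.

Problem sizes used by the tests and the acceptance script — a radius-20
ball (~33 000 voxels, ~45 000 faces), subdivision-4 icospheres (5 120
faces), 60-slice tubes — were chosen as the smallest sizes at which the
discretization errors are clearly inside the asserted tolerances; all
analytic tolerances (1% area/volume on the subdivision-4 icosphere, 5% on
the marching-cubes ball, 2% on section profiles, 15% on skeleton length)
come from the convergence behaviour of the respective discretizations, were
fixed before becoming pass criteria, and are stated next to each assertion.

## Numerical choices and degenerate inputs

* Chaining of section loops is exact (shared-edge keys), not
  tolerance-based; the only epsilon in sectioning is the 10⁻⁹·bbox on-plane
  vertex nudge.
* Nearest-vertex snapping and all skeleton searches break ties by lowest
  index, so every routine is deterministic given identical input.
* Empty volumes yield empty skeletons; single-voxel components yield a
  single node with no edges; a plane of voxels meshes to a closed pancake;
  a step longer than the center line places one mid-line plane with a
  warning; sections that miss the object produce `NA` rows, and a center
  line that misses everywhere is an error.
* OBJ files are written with 9 significant digits — faces round-trip
  exactly, vertices to ~10⁻⁷ relative.

## Known limitations

* Surface areas of voxel-derived meshes carry the iso-surface area bias
  discussed above.
* Geodesics are vertex-graph distances, not exact surface geodesics.
* The skeleton invalidation radius `scale · DBF + const` can swallow short
  side branches of very thick objects (radius comparable to branch length);
  lower `scale` recovers them at the cost of more spur pruning work.
* Meshes are assumed orientable; non-orientable input cannot be wound
  consistently and will fail the watertight test.
* No mesh repair beyond winding fixes, and no curvature/genus measures.
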