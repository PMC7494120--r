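---
title: "Shape-to-graph mapping: models, conventions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-to-graph mapping: models, conventions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapegraph)
```

## The model

`shapegraph` characterises segmented images by the generalized Voronoi
diagram of their object boundaries. The sites are all boundary vertices
(points) and all boundary segments (open segments); a graph **vertex** is
the centre of a maximal circle tangent to at least three sites with no site
strictly inside, its radius being the vertex's **clearance**; a graph
**edge** is the bisector arc between two sites — a straight line for
point/point and segment/segment pairs, a parabolic arc for point/segment
pairs. The image frame rectangle enters as four segment sites plus four
corner point sites, acting as the outermost boundary and keeping the
diagram finite. The diagram simultaneously contains the medial axis of
every object (the in-graph) and the "medial axis of the background"
(the out-graph), so it captures object widths, protrusions, and the
relative arrangement of objects in one structure. No information is
discarded: the boundaries can be recovered from the tangency structure.

All per-boundary measurements derive from two curves per (boundary, side)
subgraph:

* the **width profile** — clearance radii along the subgraph's *root path*;
* the **boundary profile** — for each point along the boundary, the shortest
  distance along subgraph edges from the root set to the graph vertex
  tangent at that point, plus that vertex's clearance (the radial drop to
  the boundary), minus the clearance of the root where the path starts.
  Points touched by a root circle therefore measure exactly zero, and a
  protrusion of length $L$ measures $\approx L$ at its tip.

Twenty summary metrics per side (profile moments and extrema; area under
the boundary profile above its 0/25/50/75% quantiles and the number of
maximal runs above each quantile; enclosed area; perimeter; the
exterior/interior flag) give the 40-dimensional per-boundary vector.
Image-level analysis clusters all boundaries of a set into $N$ *boundary
types* (k-means) and represents each image by its histogram of type counts.

## Tracing conventions

Pixel centres sit at integer coordinates; the image occupies
$[-0.5, W-0.5] \times [-0.5, H-0.5]$ and `y` increases down rows.
Boundaries are traced along the half-pixel border with the foreground on
the left of the travel direction, so exterior rings have positive shoelace
area and a one-pixel-wide line has width exactly 1 — pixel-scale features
survive. The foreground is 8-connected, background and holes 4-connected.
Where a boundary passes twice through one lattice corner (diagonally
touching pixels) the two passes are separated by 1/20 px (configurable)
in the off-diagonal direction, each point moving 1/40 px, so boundaries
never intersect or self-cross. Each shifted corner changes the enclosed
area by $\tfrac{1}{2}\cdot\sqrt2\,\cdot$ (1/40 px) $\cdot\sqrt2 \approx
0.018$ px² — negligible, and accounted for in the tests.

For label images, the largest 4-connected component of each label is traced
and every boundary point then moves halfway toward the owning pixel centre
(0.25 px inward, implemented as an exact inward offset of the rectilinear
ring). One-pixel-wide objects get width 0.5 and touching cells a half-pixel
gap, which the out-graph threads through — the background graph encodes the
spatial arrangement of all cells.

Preprocessing (`preprocess_binary()`) fills holes and removes objects
strictly below configurable area thresholds. The defaults (21 px² holes,
101 px² objects) suit experiment-like data; vector-rendered or simulated
imagery typically wants fill-only settings (e.g. holes below 100 px², no
object removal). Both are plain parameters because no single pair suits all
data.

## Graph construction

The construction is an edge-continuation (wavefront) algorithm implemented
in C++:

1. Consecutive collinear boundary segments are merged into single segment
   sites first. The union geometry is identical, but without merging every
   interior vertex of a straight run owns a degenerate zero-width Voronoi
   cell, which has no stable finite representation. The boundary polylines
   themselves keep their full vertex lists for profile sampling.
2. Every boundary corner (a point site with two incident, non-collinear
   segments) is an analytic clearance-0 vertex with exactly three known
   edges: the two perpendicular *spokes* against its own segments and the
   angular bisector of the segment pair. These corners — plus the frame
   corners, or the closest point pair for pure point input — seed the
   construction.
3. Each edge is traced along its exact bisector parametrization until the
   first site becomes co-tangent with the growing clearance circle. Event
   detection combines a Lipschitz-safe march (a step of $0.45\,g$, where
   $g$ is the smallest clearance gap among candidate sites from a uniform
   spatial grid, can never jump past a root) with closed-form caps for the
   two event families the march cannot see: the foot of the perpendicular
   leaving one of the generating segments (the event is exactly that
   segment's endpoint site becoming tangent) and a segment hanging off a
   point-site generator becoming co-tangent where the curve crosses its
   endpoint spoke. Event roots are polished by a damped 2-D Newton
   iteration on the equidistance residuals, validated against the march
   point.

Distances to open segments count only where the perpendicular foot falls
inside the segment; beyond the spokes, the endpoint point sites own the
territory. Tangency grouping uses an absolute tolerance of $10^{-7}$ px and
vertices are merged within $10^{-6}$ px. Vertices with $k \ge 4$ co-tangent
sites (ubiquitous on pixel lattices) are fanned into $k-2$ coincident
degree-3 vertices joined by zero-length edges, so **every vertex with
positive clearance has degree exactly 3**. Structure below ~1e-4 px --
tritangent circle pairs closer than the merge tolerance, micro-cells at the
1/20-px shift necks -- is collapsed: such clusters are rebuilt as chains of
coincident degree-3 vertices carrying all of the cluster's external edges,
and sub-tolerance self-loops are dropped. Well-conditioned diagrams pass
through this normalization unchanged. A segment tangent at its own endpoint shares
its tangency point with that endpoint's point site; it is ordered around
the vertex on the side of its body ($10^{-6}$-radian nudge), which fixes
the local cell combinatorics exactly.

Two deliberate exceptions to the degree-3 rule: the four frame corners keep
a single inward edge (their outward spokes leave the image), and boundary
corner vertices lie exactly *on* a boundary, so vertex side labels use four
values — `in`, `out`, `frame`, and `boundary` for clearance-0 corner
vertices, which belong to both sides as the leaves where the graph meets
the boundary. Edge sides use the three values `in`/`out`/`frame`,
determined geometrically (orientation test at a tangency foot against the
traced direction of the boundary), never by pixel lookup — pixel probing
would misassign the gap regions of the label convention.

Parabolic edge lengths use the closed-form parabola arc length; root-path
arc positions use chords between consecutive path vertices (the sagitta of
sub-pixel bisector arcs is far below all stated tolerances).

### Verification

`oracle_graph()` re-derives the diagram by brute force: for every triple of
sites, all tangent circles are found in closed form (circumcircle; circle
through two points tangent to a line; through one point tangent to two
lines; tritangent circles of three lines; plus the spoke families where a
point lies on a segment's line, which are double roots of the quadratics),
Newton-polished, and filtered by foot validity and emptiness against all
sites. The test suite requires the fast construction to match the oracle's
vertex set (positions and clearances within $10^{-6}$ px) on 100 seeded
random non-crossing segment instances, and checks emptiness, degree,
distance-transform agreement, and scale equivariance on raster fixtures.

## Root paths and profiles

Bridges are vertices equidistant to exactly two distinct boundaries (the
frame counts as boundary 0), hubs to three or more. A subgraph's root path
is the chain of its bridge/hub vertices, joined through connector vertices
where bridge runs are separated (the hole-within-a-protrusion case), and
cyclic when the chain closes; cyclic paths start at the maximal-clearance
vertex for reproducible serialization. For outermost boundaries the chain
runs through the content–frame bridge vertices (the frame-generated edges
themselves are excluded from feature extraction).

A subgraph with no bridges is a tree. Its **width profile** follows the
longest leaf-to-leaf path through the maximal-clearance root — for a
$40\times10$ bar that is the full medial-axis diameter
$30 + 10\sqrt2 \approx 44.1$ px (the ridge plus two diagonal branches).
Its **boundary profile**, however, is measured from the *single root
vertex*: using the whole diameter path as the source set would zero out
the heights of whatever protrusion the diameter happens to run through,
destroying exactly the signal the profile exists to measure (a spiked disk
must report the spike length at its tip). With bridges present, the source
set is the whole root path, each source starting at minus its clearance.

Because collinear runs are merged, boundary-profile heights are defined at
tangencies: the height at a boundary point touched by vertex $v$ is the
multi-source distance to $v$ plus clearance($v$). For a clearance-0 corner
leaf this is the plain along-graph distance; for a mid-run point under a
skeleton vertex it adds the radial drop, which makes convex shapes measure
uniformly $\approx 0$. Heights are sampled at every traced boundary vertex
from the circularly nearest tangency (minimal height on ties). Quantiles
use R's default linear interpolation; "crossings" count maximal cyclic runs
above the quantile (at the 0th quantile: runs attaining the minimum within
$10^{-9}$), making the counts independent of the traversal start.

## Boundary typing and downstream analyses

Features are standardized per column by median/IQR before k-means
(zero-IQR columns are dropped from the distance); the 40 metrics span
incommensurate units, and robust scaling resists the heavy tails of
area-like features. k-means uses k-means++ seeding with 10 restarts under a fixed
seed, keeping the best-inertia solution;
nearest-centroid ties break toward the lowest type index. k-NN
classification (default $k=3$, leave-one-out, Euclidean distance on raw
counts; frequencies by option) breaks voting ties by the nearest single
neighbour. Regression of log-transformed generative parameters on type
counts is ordinary least squares evaluated by leave-one-out; a type absent
from a training fold drops out with coefficient zero (`lm()` aliasing
semantics), and an explicit ridge penalty is available. Per-well vectors
are the mean and population-SD of the per-cell metrics (flag dropped):
$4 \times 19 = 76$ values; wells are normalized by subtracting the median
vector of each plate's control wells; held-out-plate classification uses a
CART decision tree (Gini impurity, grown to purity -- depth-unlimited, no
complexity pruning -- under a fixed seed) and reports
per-class F1 and the unweighted macro mean.

## The synthetic generators

`make_primitive()` rasterises disks, annuli, bars, and spiked disks with
analytically known area, inradius and protrusion length. `make_mesh()`
emulates multicellular network images phenomenologically: seeds scattered
with a minimum spacing, neighbour pairs (within three median
nearest-neighbour distances) joined independently with probability
`connectivity`, struts of half-width `density`, blobs of radius
`density + 1.5`. It guarantees the monotone relationships the recovery
analyses need — expected hole count grows with connectivity, mean
foreground width with density — and nothing more: it does not simulate
cell mechanics, adhesion kinetics, or any biophysical model, and passing
its tests shows the *pipeline* recovers structure from images with these
statistics, not that it reproduces any particular biology.
`make_label_mosaic()` tessellates the frame by nearest seed for the
label-image convention. All generators are deterministic under a fixed
seed and emit their ground truth as attributes.

The parameter-recovery analysis in the test suite uses a $10\times10$ grid
of (connectivity, density) — one seeded realization each, 100 images of
$144^2$ px with 50 seeds, roughly 50 boundaries per image. The problem
sizes balance statistical richness (histograms need enough boundaries per
image for 12-type counts to be stable) against the cost of building one
graph per image; they are the package's default study conditions for this
analysis, stated here so the numbers are reproducible.

## Known limitations

* Boundaries touching the image frame are rejected rather than clipped;
  callers should pad segmented images by a few background pixels.
* The anti-crossing shift makes boundaries simple but creates features at
  the 1/20-px scale; tolerances below that (tangency $10^{-7}$, merge
  $10^{-6}$) must not be loosened.
* Sub-tolerance structure (tritangent circle pairs closer than $10^{-6}$
  px) is collapsed; counts of zero-length edges are therefore
  convention-dependent, while vertex positions and clearances are not.
* The no-bridge root path absorbs the longest protrusion into the width
  profile by construction; the boundary profile compensates (see above),
  but per-boundary width moments of strongly star-shaped objects should be
  read with that in mind.
* Grayscale segmentation is out of scope: the graph is only as good as the
  input mask, and over-/under-thresholded masks yield faithfully wrong
  graphs.
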