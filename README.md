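# shapegraph

Shape-to-graph morphometry for segmented biological images.

Many quantification problems in cell biology — tube-formation (angiogenesis)
assays, phenotypic screens of segmented cell cultures, simulated multicellular
patterns — come down to describing *arbitrarily complex* shapes: meshes,
branching networks, blobs with protrusions, and the spaces between them.
Classical morphometrics (solidity, eccentricity, skeleton statistics) either
assume compact objects or throw away geometry during thinning.

`shapegraph` instead maps **all** object boundaries in an image onto a single
generalized Voronoi graph and measures that graph:

* Boundaries are traced along the **half-pixel border** between foreground
  and background, so a one-pixel line has width exactly 1; diagonally
  touching pixels are disambiguated by a 1/20-px off-diagonal shift. For
  label images (one label per cell), boundary points move halfway toward the
  pixel centre, giving touching cells a half-pixel gap and one-pixel objects
  width 0.5.
* The **generalized Voronoi diagram** of all boundary vertices (point sites)
  and boundary segments (open segment sites), bounded by the image frame, is
  built exactly: each graph vertex is the centre of a maximal circle tangent
  to ≥ 3 sites with no site inside (its *clearance*), and each edge is a
  line or parabolic bisector arc. Every vertex has degree 3 (degenerate
  co-circular tangencies are split into coincident degree-3 vertices joined
  by zero-length edges).
* The graph is annotated into the **in-graph** (foreground) and **out-graph**
  (background); vertices equidistant to two boundaries are *bridges*, to
  three or more *hubs*; each boundary owns one subgraph per side, bounded by
  its **root path**.
* Per subgraph, the **width profile** (clearance radii along the root path)
  and the **boundary profile** (shortest along-graph distance from the root
  set to each boundary point, minus the root clearance) summarise into
  **20 metrics per side, 40 per boundary**: profile moments and extrema,
  area-under-curve and crossing counts above the 0/25/50/75% quantiles,
  enclosed area, perimeter, and the exterior/interior flag.
* Image sets are compared by **k-means boundary types**: per-image histograms
  of type counts feed PCA, leave-one-out k-NN classification, and linear
  regression of generative parameters. Per-cell features aggregate to
  **76-value well vectors** (mean and SD of the 19 + 19 per-cell metrics)
  with plate-control normalization and held-out-plate decision-tree
  classification scored by per-class F1 = 2·precision·recall /
  (precision + recall).

A brute-force tangent-circle oracle (`oracle_graph()`) reconstructs the
diagram in O(n³) by closed-form enumeration and verifies the fast
construction in the test suite. Seeded generators (`make_primitive()`,
`make_mesh()`, `make_label_mosaic()`) provide fixtures with known ground
truth, so every stage is testable without external data.

## Worked example

```r
library(shapegraph)

img <- make_primitive("annulus", size = 96, r = 21, r_inner = 13)
b   <- trace_binary_boundaries(img)
b
#> # A tibble: 2 × 6
#>   boundary_id kind     owner  area perimeter points
#>         <int> <chr>    <int> <dbl>     <dbl> <list>
#> 1           1 exterior     1  1396       168 <dbl [168 x 2]>
#> 2           2 interior     1   540       104 <dbl [104 x 2]>

g <- annotate_graph(build_shape_graph(b))
g
#> <shape_graph> 646 vertices, 965 edges, 328 sites, 2 boundaries
#>   sides: boundary=160 frame=4 in=240 out=242

sg <- subgraph_of(g, 1, "in")
wp <- width_profile(sg)       # clearance radii along the looped root path
mean(wp$radius)
#> [1] 3.658042

f <- boundary_features(g, 1)  # the 40 metrics of boundary 1
round(f[c("in_width_mean", "in_width_max", "in_bnd_max", "in_area")], 3)
#> in_width_mean  in_width_max    in_bnd_max       in_area
#>         3.658         4.000         0.858      1396.000
```

The material of the annulus is (21 − 13) = 8 px thick, so the in-graph width
profile sits at radius ≈ 4 (3.66 along the staircase ridge); the boundary profile stays near zero (a convex
ring has no protrusions); `in_area` is the enclosed pixel count. For image
sets, `extract_features_set()` + `fit_boundary_types()` +
`image_histograms()` chain into `knn_classify()` /
`fit_param_regression()` / `holdout_plate_classify()`.

A thin command-line wrapper is installed at
`system.file("cli", "shapegraph.R", package = "shapegraph")` with
`extract`, `analyze`, `synth`, and `verify` subcommands.

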