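annulus_graph <- function() {
  cached("annulus_graph", {
    img <- make_primitive("annulus", size = 96, r = 21, r_inner = 13)
    annotate_graph(build_shape_graph(trace_binary_boundaries(img)))
  })
}

disks3_graph <- function() {
  cached("disks3_graph", {
    m <- matrix(0L, 64, 64)
    xs <- matrix(rep(0:63, each = 64), 64); ys <- matrix(rep(0:63, 64), 64)
    for (c0 in list(c(18, 18), c(45, 20), c(30, 45))) {
      m[(xs - c0[1])^2 + (ys - c0[2])^2 <= 64] <- 1L
    }
    annotate_graph(build_shape_graph(trace_binary_boundaries(
      raster_image(m, "binary"))))
  })
}

test_that("in/out labels partition the vertices of a disk image", {
  img <- make_primitive("disk", size = 64, r = 13)
  g <- annotate_graph(build_shape_graph(trace_binary_boundaries(img)))
  v <- g$vertices
  expect_true(all(v$side %in% c("in", "out", "frame", "boundary")))
  expect_equal(sum(table(v$side)), nrow(v))   # conservation
  # inside-disk vertices are labelled in, gap vertices out
  cx <- 31.5; cy <- 31.5
  d <- sqrt((v$x - cx)^2 + (v$y - cy)^2)
  pos <- v$clearance > 1e-7
  expect_true(all(v$side[pos & d < 12] == "in"))
  expect_true(all(v$side[pos & d > 14.6 &
                           v$side != "frame"] == "out"))
  # edges carry the three spec labels
  expect_true(all(g$edges$side %in% c("in", "out", "frame")))
})

test_that("the annulus has a looped bridge between its two boundaries", {
  g <- annulus_graph()
  sg <- subgraph_of(g, 1, "in")
  rp <- root_path(sg)
  expect_true(rp$cyclic)
  roles <- g$vertices$role[rp$vertex_ids]
  expect_true(all(roles %in% c("bridge", "hub", "connector")))
  eq <- g$vertices$equidistant[rp$vertex_ids]
  expect_true(all(vapply(eq, function(b) identical(b, c(1L, 2L)), logical(1))))
  # no hubs in the material: only two boundaries exist inside
  vin <- g$vertices$role[g$vertices$side == "in"]
  expect_equal(sum(vin == "hub"), 0)
  # material width ~ (21 - 13) / 2
  wp <- width_profile(sg)
  expect_equal(mean(wp$radius), 4, tolerance = 0.5)
})

test_that("hubs appear where three boundaries meet in the background", {
  g <- disks3_graph()
  vout <- g$vertices[g$vertices$side == "out", ]
  expect_gt(sum(vout$role == "hub"), 0)
  hub <- vout[vout$role == "hub", ]
  expect_true(any(vapply(hub$equidistant, function(b) {
    length(setdiff(b, 0L)) >= 3
  }, logical(1))))
})

test_that("a single convex object has no bridges in its in-graph", {
  img <- make_primitive("disk", size = 56, r = 11)
  g <- annotate_graph(build_shape_graph(trace_binary_boundaries(img)))
  vin <- g$vertices[g$vertices$side == "in", ]
  expect_equal(sum(vin$role %in% c("bridge", "hub")), 0)
  rp <- root_path(subgraph_of(g, 1, "in"))
  expect_false(rp$cyclic)
  expect_false(rp$has_bridges)
})

test_that("subgraph partition covers all non-frame edges exactly once", {
  for (g in list(annulus_graph(), disks3_graph())) {
    parts <- partition_subgraphs(g)
    # unique ownership from owner_boundary x side
    e <- g$edges[g$edges$side %in% c("in", "out"), ]
    own <- paste(e$owner_boundary, e$side)
    expect_equal(length(own), nrow(e))
    expect_true(all(e$owner_boundary > 0))
    # inclusive subgraph edge sets cover every content edge
    covered <- sort(unique(unlist(parts$edge_ids)))
    expect_equal(covered, sort(which(g$edges$side %in% c("in", "out"))))
  }
  # annulus: exactly 2 in-subgraphs and 2 out-subgraphs
  parts <- partition_subgraphs(annulus_graph())
  expect_equal(nrow(parts[parts$side == "in", ]), 2)
  expect_equal(nrow(parts[parts$side == "out", ]), 2)
})

test_that("every boundary owns one subgraph per side", {
  g <- disks3_graph()
  parts <- partition_subgraphs(g)
  for (b in g$boundaries$boundary_id) {
    expect_equal(sum(parts$boundary_id == b & parts$side == "in"), 1)
    expect_equal(sum(parts$boundary_id == b & parts$side == "out"), 1)
  }
})

test_that("bridge sets match brute-force boundary distances", {
  g <- annulus_graph()
  v <- g$vertices[g$vertices$role == "bridge" & g$vertices$side == "in", ]
  v <- v[unique(round(seq(1, nrow(v), length.out = min(8, nrow(v))))), ]
  segs <- shapegraph:::boundaries_segments(g$boundaries)
  for (i in seq_len(nrow(v))) {
    d <- vapply(split(segs, segs$boundary_id), function(ss) {
      px <- v$x[i]; py <- v$y[i]
      min(vapply(seq_len(nrow(ss)), function(k) {
        ux <- ss$x2[k] - ss$x1[k]; uy <- ss$y2[k] - ss$y1[k]
        L <- sqrt(ux^2 + uy^2); ux <- ux / L; uy <- uy / L
        t <- pmin(pmax((px - ss$x1[k]) * ux + (py - ss$y1[k]) * uy, 0), L)
        sqrt((px - (ss$x1[k] + t * ux))^2 + (py - (ss$y1[k] + t * uy))^2)
      }, numeric(1)))
    }, numeric(1))
    eq <- as.integer(names(d))[abs(d - min(d)) < 1e-6]
    expect_equal(sort(eq), setdiff(v$equidistant[[i]], 0L))
  }
})

test_that("the bar root path is the medial-axis diameter through the root", {
  img <- make_primitive("bar", size = 64, width = 40, height = 10)
  g <- annotate_graph(build_shape_graph(trace_binary_boundaries(img)))
  rp <- root_path(subgraph_of(g, 1, "in"))
  # medial axis of a 40 x 10 rectangle: 30-px horizontal ridge plus two
  # diagonal branches of length 5 * sqrt(2) at each end
  expect_equal(max(rp$arc), 30 + 10 * sqrt(2), tolerance = 2)
  # the ridge is a single 30-px edge on the horizontal midline between the
  # two degree-3 junctions at clearance 5 (collinear runs are merged)
  mid <- rp$vertex_ids[abs(g$vertices$clearance[rp$vertex_ids] - 5) < 1e-6]
  expect_equal(length(mid), 2)
  expect_equal(g$vertices$y[mid], c(31.5, 31.5))
  expect_equal(abs(diff(g$vertices$x[mid])), 30)
  # root-path vertices are bridges/connectors whenever bridges exist
  g2 <- annulus_graph()
  rp2 <- root_path(subgraph_of(g2, 1, "in"))
  expect_true(all(g2$vertices$role[rp2$vertex_ids] != "branch"))
})

test_that("removing the root path splits a bridged subgraph into boundary-touching trees", {
  g <- annulus_graph()
  sg <- subgraph_of(g, 1, "in")
  rp <- root_path(sg)
  e <- g$edges[sg$edge_ids, ]
  keep <- !(e$v1 %in% rp$vertex_ids) & !(e$v2 %in% rp$vertex_ids)
  e2 <- e[keep & !is.na(e$v2), ]
  if (nrow(e2)) {
    ig <- igraph::graph_from_edgelist(cbind(as.character(e2$v1),
                                            as.character(e2$v2)),
                                      directed = FALSE)
    comps <- igraph::components(ig)
    member <- split(names(comps$membership), comps$membership)
    # every remaining component touches the boundary (has a leaf vertex
    # with near-zero clearance)
    touches <- vapply(member, function(vs) {
      any(g$vertices$clearance[as.integer(vs)] < 1e-6)
    }, logical(1))
    expect_true(all(touches))
  }
  expect_error(root_path(subgraph_of(g, 1, "out")), NA)
})
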