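test_that("width profiles agree with the distance transform", {
  fixtures <- list(
    disk = make_primitive("disk", size = 72, r = 15),
    annulus = make_primitive("annulus", size = 96, r = 21, r_inner = 13),
    bar = make_primitive("bar", size = 64, width = 40, height = 11)
  )
  for (nm in names(fixtures)) {
    g <- annotate_graph(build_shape_graph(trace_binary_boundaries(
      fixtures[[nm]])))
    sg <- subgraph_of(g, 1, "in")
    rp <- root_path(sg)
    wp <- width_profile(sg, rp)
    xy <- cbind(g$vertices$x[attr(wp, "vertex_ids")],
                g$vertices$y[attr(wp, "vertex_ids")])
    ref <- bg_clearance_at(fixtures[[nm]], xy[, 1], xy[, 2])
    expect_lt(max(abs(wp$radius - ref)), 0.5)
    expect_true(all(diff(wp$arc) > 0))
    expect_true(all(wp$radius > 0))
    expect_lte(min(wp$radius), mean(wp$radius))
    expect_lte(mean(wp$radius), max(wp$radius))
  }
})

test_that("the 1x5 bar has maximal inscribed width exactly one pixel", {
  m <- matrix(0L, 11, 11); m[6, 4:8] <- 1L
  g <- annotate_graph(build_shape_graph(trace_binary_boundaries(
    raster_image(m, "binary"))))
  wp <- width_profile(subgraph_of(g, 1, "in"))
  expect_equal(2 * max(wp$radius), 1, tolerance = 1e-9)
})

test_that("boundary profiles are flat for convex shapes and see protrusions", {
  img <- make_primitive("disk", size = 110, r = 25)
  g <- annotate_graph(build_shape_graph(trace_binary_boundaries(img)))
  bp <- boundary_profile(subgraph_of(g, 1, "in"))
  expect_lt(max(bp$height), 2)        # pixelation only
  expect_gt(min(bp$height), -1e-6)
  expect_equal(max(abs(diff(bp$arc))), 1, tolerance = 1e-9)

  img2 <- make_primitive("spiked_disk", size = 110, r = 20, spike = 10)
  g2 <- annotate_graph(build_shape_graph(trace_binary_boundaries(img2)))
  bp2 <- boundary_profile(subgraph_of(g2, 1, "in"))
  expect_equal(max(bp2$height), 10, tolerance = 1.5)
  # the maximum sits at the spike tip
  ring <- g2$boundaries$points[[1]]
  tip_x <- max(ring[, 1])
  at_max <- ring[which.max(bp2$height), ]
  expect_gt(at_max[1], tip_x - 2.5)
})

test_that("heights vanish at the root circle's tangency points", {
  img <- make_primitive("bar", size = 64, width = 40, height = 10)
  g <- annotate_graph(build_shape_graph(trace_binary_boundaries(img)))
  sg <- subgraph_of(g, 1, "in")
  rp <- root_path(sg)
  bp <- boundary_profile(sg, rp)
  # boundary points tangent to the root vertex's circle measure ~ 0
  tg <- g$tangents[g$tangents$vertex_id == rp$root_id, ]
  tg <- tg[g$sites$boundary_id[tg$site_id] == 1, ]
  ring <- g$boundaries$points[[1]]
  for (k in seq_len(nrow(tg))) {
    d <- sqrt((ring[, 1] - tg$tx[k])^2 + (ring[, 2] - tg$ty[k])^2)
    expect_lt(abs(bp$height[which.min(d)]), 0.5)
  }
  expect_gt(min(bp$height), -1e-6)
  # with a single root at one ridge junction, the farthest corner leaf sits
  # at ridge length + diagonal branch - root clearance along the graph
  expect_equal(max(bp$height), 30 + 5 * sqrt(2) - 5, tolerance = 3)
})

test_that("multi-source heights match an independent Dijkstra", {
  g <- cached("annulus_graph", {
    img <- make_primitive("annulus", size = 96, r = 21, r_inner = 13)
    annotate_graph(build_shape_graph(trace_binary_boundaries(img)))
  })
  sg <- subgraph_of(g, 1, "in")
  rp <- root_path(sg)
  hts <- shapegraph:::subgraph_heights(sg, rp)
  # independent recomputation with igraph on the same edge list
  e <- g$edges[sg$edge_ids, ]
  e <- e[!is.na(e$v2), ]
  ig <- igraph::graph_from_edgelist(cbind(as.character(e$v1),
                                          as.character(e$v2)),
                                    directed = FALSE)
  igraph::E(ig)$w <- pmax(e$length, 0)
  roots <- as.character(rp$vertex_ids)
  roots <- roots[roots %in% igraph::V(ig)$name]
  dmat <- igraph::distances(ig, v = roots, weights = igraph::E(ig)$w)
  off <- g$vertices$clearance[as.integer(roots)]
  ref <- apply(dmat - off, 2, min)
  common <- intersect(names(hts), names(ref))
  expect_equal(hts[common], ref[common], tolerance = 1e-10)
})

test_that("boundary feature vectors have 40 entries in fixed order", {
  g <- cached("annulus_graph", {
    img <- make_primitive("annulus", size = 96, r = 21, r_inner = 13)
    annotate_graph(build_shape_graph(trace_binary_boundaries(img)))
  })
  f <- boundary_features(g, 1)
  expect_length(f, 40)
  expect_identical(names(f), feature_names())
  # AUC monotone across quantiles, both sides
  for (side in c("in", "out")) {
    auc <- f[paste0(side, "_", c("auc_q0", "auc_q25", "auc_q50", "auc_q75"))]
    expect_true(all(diff(auc) <= 1e-9))
  }
  # area/perimeter/flag agree with tracing and are identical between sides
  expect_equal(unname(f["in_area"]), g$boundaries$area[1])
  expect_equal(unname(f["in_perimeter"]), g$boundaries$perimeter[1])
  expect_equal(unname(f["in_exterior"]), 1)
  expect_equal(unname(f["in_area"]), unname(f["out_area"]))
  expect_equal(unname(f["in_exterior"]), unname(f["out_exterior"]))
  f2 <- boundary_features(g, 2)
  expect_equal(unname(f2["in_exterior"]), 0)
})

test_that("protrusion length is recovered across a sweep of spike lengths", {
  for (L in c(5, 20)) {
    img <- make_primitive("spiked_disk", size = 90 + 2 * L, r = 18, spike = L)
    g <- annotate_graph(build_shape_graph(trace_binary_boundaries(img)))
    bp <- boundary_profile(subgraph_of(g, 1, "in"))
    expect_equal(max(bp$height), L, tolerance = 0.15 * L + 1,
                 info = paste("L =", L))
  }
})

test_that("scaling the image scales width-profile radii", {
  img1 <- make_primitive("annulus", size = 64, r = 14, r_inner = 8)
  img2 <- make_primitive("annulus", size = 128, r = 28, r_inner = 16)
  w1 <- width_profile(subgraph_of(annotate_graph(build_shape_graph(
    trace_binary_boundaries(img1))), 1, "in"))
  w2 <- width_profile(subgraph_of(annotate_graph(build_shape_graph(
    trace_binary_boundaries(img2))), 1, "in"))
  expect_equal(mean(w2$radius) / mean(w1$radius), 2, tolerance = 0.15)
})

test_that("cyclic run counting is start-independent", {
  expect_equal(shapegraph:::run_count(c(TRUE, FALSE, TRUE, TRUE, FALSE)), 2L)
  expect_equal(shapegraph:::run_count(c(TRUE, FALSE, TRUE, TRUE, TRUE)), 1L)
  expect_equal(shapegraph:::run_count(rep(TRUE, 4)), 1L)
  expect_equal(shapegraph:::run_count(rep(FALSE, 4)), 0L)
})
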