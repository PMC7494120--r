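test_that("point-only diagrams match closed-form geometry", {
  # circumcircle of a right triangle
  g <- voronoi_diagram(rbind(c(0, 0), c(4, 0), c(0, 3)))
  expect_equal(nrow(g$vertices), 1)
  expect_equal(g$vertices$x, 2)
  expect_equal(g$vertices$y, 1.5)
  expect_equal(g$vertices$clearance, 2.5)

  # four cocircular points: two coincident degree-3 vertices joined by a
  # zero-length edge
  g2 <- voronoi_diagram(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_equal(nrow(g2$vertices), 2)
  expect_equal(g2$vertices$x, c(0.5, 0.5))
  expect_equal(g2$vertices$y, c(0.5, 0.5))
  expect_equal(g2$vertices$clearance, rep(sqrt(0.5), 2), tolerance = 1e-9)
  zl <- g2$edges[!is.na(g2$edges$v2) & g2$edges$v1 != g2$edges$v2, ]
  expect_true(any(zl$length == 0))
})

test_that("the in-graph of a solid square attains the inradius", {
  m <- matrix(0L, 18, 18); m[4:14, 4:14] <- 1L   # 11x11 square
  g <- build_shape_graph(trace_binary_boundaries(raster_image(m, "binary")))
  ga <- annotate_graph(g)
  vin <- ga$vertices[ga$vertices$side == "in", ]
  expect_equal(max(vin$clearance), 5.5, tolerance = 1e-9)
})

test_that("every positive-clearance vertex has degree exactly 3", {
  imgs <- list(
    make_primitive("disk", size = 64, r = 12),
    make_primitive("annulus", size = 72, r = 16, r_inner = 9),
    make_mesh(0.7, 1.6, n_seeds = 12, size = 80, seed = 5)
  )
  for (img in imgs) {
    g <- build_shape_graph(trace_binary_boundaries(img))
    deg <- tabulate(c(g$edges$v1, g$edges$v2[!is.na(g$edges$v2)]),
                    nbins = nrow(g$vertices))
    pos <- g$vertices$clearance > 1e-7
    expect_true(all(deg[pos] == 3))
    # content corners (clearance 0 off the frame) are degree 3 too; only
    # the four frame corners keep a single inward edge
    fr <- g$frame
    corner <- (abs(g$vertices$x - fr[1]) < 1e-9 |
                 abs(g$vertices$x - fr[3]) < 1e-9) &
      (abs(g$vertices$y - fr[2]) < 1e-9 | abs(g$vertices$y - fr[4]) < 1e-9)
    expect_true(all(deg[!pos & !corner] == 3))
    expect_true(all(deg[corner] == 1))
  }
})

test_that("clearance circles are empty and tangent to >= 3 sites", {
  img <- make_primitive("annulus", size = 72, r = 16, r_inner = 9)
  g <- build_shape_graph(trace_binary_boundaries(img))
  sites <- g$sites
  n <- nrow(sites)
  for (i in seq_len(nrow(g$vertices))) {
    r <- g$vertices$clearance[i]
    dcl <- vapply(seq_len(n), function(j) {
      shapegraph:::oracle_dclosed(sites, j, g$vertices$x[i], g$vertices$y[i])
    }, numeric(1))
    expect_gt(min(dcl), r - 1e-6)
    expect_lt(abs(min(dcl) - r), 1e-6)
  }
  tab <- table(g$tangents$vertex_id)
  expect_true(all(tab == 3))  # after fan splitting every vertex has 3
})

test_that("build_graph matches the tangent-circle oracle on random sites", {
  for (seed in 1:12) {
    rs <- random_segment_sites(6, seed)
    ge <- voronoi_diagram(rs$points, rs$segments, rs$p1, rs$p2,
                          frame = rs$frame)
    go <- oracle_of_sites(ge$sites)
    expect_same_vertices(ge, go)
  }
})

test_that("oracle refuses instances above its size cap", {
  rs <- random_segment_sites(8, 1)
  ge <- voronoi_diagram(rs$points, rs$segments, rs$p1, rs$p2,
                        frame = rs$frame)
  expect_error(oracle_of_sites(ge$sites, cap = 10),
               class = "shapegraph_size_error")
})

test_that("doubling resolution scales positions and clearances by two", {
  img1 <- make_primitive("disk", size = 60, r = 11)
  img2 <- make_primitive("disk", size = 120, r = 22)
  g1 <- annotate_graph(build_shape_graph(trace_binary_boundaries(img1)))
  g2 <- annotate_graph(build_shape_graph(trace_binary_boundaries(img2)))
  c1 <- max(g1$vertices$clearance[g1$vertices$side == "in"])
  c2 <- max(g2$vertices$clearance[g2$vertices$side == "in"])
  expect_equal(c2 / c1, 2, tolerance = 0.1)  # rasterization error only
})

test_that("the maximal-clearance vertex sits at the distance-transform max", {
  for (img in list(make_primitive("disk", size = 56, r = 11),
                   make_primitive("bar", size = 56, width = 25, height = 13))) {
    g <- annotate_graph(build_shape_graph(trace_binary_boundaries(img)))
    vin <- g$vertices[g$vertices$side == "in", ]
    best <- vin[which.max(vin$clearance), ]
    dm <- dt_max(img)
    # the pixel-centre distance transform undersamples the true maximum by
    # at most half a pixel diagonal, and locates it only to the pixel grid
    # (plateaus for ridge-shaped maxima); the vertex must be at least as
    # deep and lie on the plateau
    expect_gte(best$clearance, dm$value - 1e-9)
    expect_lt(best$clearance - dm$value, sqrt(2) / 2 + 1e-9)
    plateau_d <- bg_clearance_at(img, best$x, best$y)
    expect_lt(dm$value - plateau_d, 0.5)  # the vertex is on the DT plateau
  }
})

test_that("crossing input boundaries raise a geometry error naming the pair", {
  m <- matrix(0L, 10, 10); m[3:5, 3:5] <- 1L; m[7:8, 7:8] <- 1L
  b <- trace_binary_boundaries(raster_image(m, "binary"))
  # corrupt: shift boundary 2 so its ring crosses boundary 1's ring
  b$points[[2]] <- b$points[[2]] - 3
  expect_error(build_shape_graph(b), "1 and 2",
               class = "shapegraph_geometry_error")
})
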