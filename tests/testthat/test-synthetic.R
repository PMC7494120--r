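test_that("primitives have analytically known geometry", {
  img <- make_primitive("disk", size = 128, r = 25)
  expect_equal(sum(img$values), pi * 25^2, tolerance = 0.01 * pi * 25^2)
  b <- trace_binary_boundaries(img)
  expect_equal(nrow(b), 1)

  ann <- make_primitive("annulus", size = 128, r = 30, r_inner = 20)
  ba <- trace_binary_boundaries(ann)
  expect_equal(sort(ba$kind), c("exterior", "interior"))
  expect_equal(sum(ann$values), pi * (30^2 - 20^2),
               tolerance = 0.02 * pi * (30^2 - 20^2))

  bar <- make_primitive("bar", size = 64, width = 40, height = 10)
  expect_equal(sum(bar$values), 400)

  sp <- make_primitive("spiked_disk", size = 110, r = 20, spike = 10)
  expect_gt(sum(sp$values), pi * 400)
  expect_error(make_primitive("disk", size = 40, r = 25),
               class = "shapegraph_geometry_error")
})

test_that("mesh generator respects connectivity and density monotonically", {
  # connectivity 0: one component per seed blob, no struts
  img0 <- make_mesh(0, 2, n_seeds = 10, size = 96, seed = 2)
  expect_equal(attr(img0, "n_struts"), 0)
  expect_equal(attr(flood_count(img0$values, 8), "n"), 10)

  # connectivity 1 with dense seeds: a single component with holes
  img1 <- make_mesh(1, 2, n_seeds = 16, size = 96, seed = 2)
  expect_equal(attr(flood_count(img1$values, 8), "n"), 1)
  expect_gt(hole_count(img1$values), 0)

  # expected hole count grows with connectivity (averaged over seeds)
  holes <- function(conn) {
    mean(vapply(1:6, function(s) {
      hole_count(make_mesh(conn, 1.6, n_seeds = 14, size = 96,
                           seed = 100 + s)$values)
    }, numeric(1)))
  }
  expect_gt(holes(0.9), holes(0.3))

  # doubling density roughly doubles the mean width-profile radius
  widths <- function(dens) {
    mean(vapply(1:6, function(s) {
      img <- make_mesh(0.8, dens, n_seeds = 10, size = 96, seed = 200 + s)
      g <- annotate_graph(build_shape_graph(trace_binary_boundaries(img)))
      ext <- g$boundaries$boundary_id[g$boundaries$kind == "exterior"]
      mean(vapply(ext, function(b) {
        mean(width_profile(subgraph_of(g, b, "in"))$radius)
      }, numeric(1)))
    }, numeric(1)))
  }
  expect_equal(widths(2.4) / widths(1.2), 2, tolerance = 0.35)
})

test_that("generators are deterministic under a fixed seed", {
  a <- make_mesh(0.6, 1.7, n_seeds = 12, size = 80, seed = 42)
  b <- make_mesh(0.6, 1.7, n_seeds = 12, size = 80, seed = 42)
  expect_identical(a$values, b$values)
  c1 <- make_label_mosaic(6, size = 48, seed = 9)
  c2 <- make_label_mosaic(6, size = 48, seed = 9)
  expect_identical(c1$values, c2$values)
})

test_that("label mosaics tessellate the frame with adjacency ground truth", {
  mo <- make_label_mosaic(1, size = 32, seed = 1)
  expect_true(all(mo$values == 1L))
  b1 <- trace_label_boundaries(mo)
  expect_equal(nrow(b1), 1)

  mo8 <- make_label_mosaic(8, size = 64, seed = 3)
  expect_equal(sort(unique(as.vector(mo8$values))), 1:8)
  b8 <- trace_label_boundaries(mo8)
  expect_equal(sort(unique(b8$owner)), 1:8)
  adj <- attr(mo8, "adjacency")
  expect_true(nrow(adj) >= 7)  # a tessellation is connected

  # adjacent labels' traced boundaries are 0.5 px apart at their interface
  pair <- adj[1, ]
  p1 <- b8$points[[which(b8$owner == pair[1])[1]]]
  p2 <- b8$points[[which(b8$owner == pair[2])[1]]]
  dmin <- min(vapply(seq_len(nrow(p1)), function(i) {
    min(sqrt((p2[, 1] - p1[i, 1])^2 + (p2[, 2] - p1[i, 2])^2))
  }, numeric(1)))
  expect_equal(dmin, 0.5, tolerance = 0.05)
})

test_that("raster io round-trips masks and labels", {
  img <- make_primitive("disk", size = 48, r = 9)
  p <- tempfile(fileext = ".png")
  write_raster(img, p)
  back <- read_raster(p, "binary")
  expect_identical(back$values, img$values)

  mo <- make_label_mosaic(5, size = 32, seed = 2)
  p2 <- tempfile(fileext = ".tif")
  write_raster(mo, p2)
  back2 <- read_raster(p2, "label")
  expect_identical(back2$values, mo$values)
})
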