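test_that("preprocessing fills small holes and removes small objects", {
  m <- matrix(0L, 20, 20)
  m[5:12, 5:12] <- 1L          # 64-px object
  m[8:9, 8:11] <- 0L           # 8-px hole
  m[16:17, 16:17] <- 0L        # (background, outside object)
  m[2, 2] <- 1L                # 1-px debris (part of nothing)
  m[15:16, 3] <- 1L            # 2-px debris
  img <- raster_image(m, "binary")

  filt <- preprocess_binary(img, min_hole_area = 21, min_object_area = 50)
  b <- trace_binary_boundaries(filt)
  expect_equal(sum(b$kind == "interior"), 0)   # hole filled
  expect_equal(sum(b$kind == "exterior"), 1)   # debris removed
  expect_equal(sum(filt$values), 64)           # full square restored

  # thresholds (0, 0): identity
  expect_identical(preprocess_binary(img, 0, 0)$values, img$values)

  # a hole at the threshold is kept (strictly-below rule)
  keep <- preprocess_binary(img, min_hole_area = 8, min_object_area = 0)
  expect_equal(sum(trace_binary_boundaries(keep)$kind == "interior"), 1)

  expect_error(preprocess_binary(raster_image(m, "label")),
               class = "shapegraph_mode_error")
})

test_that("half-pixel tracing of elementary shapes", {
  # single pixel: unit square, area 1, perimeter 4
  m <- matrix(0L, 7, 7); m[4, 4] <- 1L
  b <- trace_binary_boundaries(raster_image(m, "binary"))
  expect_equal(nrow(b), 1)
  expect_equal(b$kind, "exterior")
  expect_equal(b$area, 1)
  expect_equal(b$perimeter, 4)
  p <- b$points[[1]]
  expect_true(all(p[, 1] %in% c(2.5, 3.5) & p[, 2] %in% c(2.5, 3.5)))

  # 1x5 bar: 1x5 rectangle
  m2 <- matrix(0L, 11, 11); m2[6, 4:8] <- 1L
  b2 <- trace_binary_boundaries(raster_image(m2, "binary"))
  expect_equal(b2$area, 5)
  expect_equal(b2$perimeter, 12)
})

test_that("diagonal contact is joined with the 1/20 px anti-crossing shift", {
  m <- matrix(0L, 8, 8); m[4, 4] <- 1L; m[5, 5] <- 1L
  b <- trace_binary_boundaries(raster_image(m, "binary"))
  expect_equal(nrow(b), 1)  # 8-connected: one object, one boundary
  p <- b$points[[1]]
  near <- p[abs(p[, 1] - 3.5) < 0.2 & abs(p[, 2] - 3.5) < 0.2, ]
  expect_equal(nrow(near), 2)
  expect_equal(sqrt(sum((near[1, ] - near[2, ])^2)), 0.05, tolerance = 1e-12)
  expect_silent(assert_boundaries_simple(b))
  # area changed only by the shift wedges (< 0.02 px^2 per shifted corner)
  expect_lt(abs(b$area - 2), 2 * 0.02)
  # configurable shift
  b2 <- trace_binary_boundaries(raster_image(m, "binary"), shift = 0.2)
  p2 <- b2$points[[1]]
  near2 <- p2[abs(p2[, 1] - 3.5) < 0.3 & abs(p2[, 2] - 3.5) < 0.3, ]
  expect_equal(sqrt(sum((near2[1, ] - near2[2, ])^2)), 0.2, tolerance = 1e-12)
})

test_that("boundary counts equal component and hole counts on random masks", {
  for (seed in 1:6) {
    set.seed(seed)
    m <- matrix(as.integer(stats::runif(26 * 26) < 0.45), 26, 26)
    m[c(1, 26), ] <- 0L; m[, c(1, 26)] <- 0L
    img <- raster_image(m, "binary")
    b <- trace_binary_boundaries(img)
    expect_equal(sum(b$kind == "exterior"), attr(flood_count(m, 8), "n"),
                 info = paste("seed", seed))
    expect_equal(sum(b$kind == "interior"), hole_count(m),
                 info = paste("seed", seed))
    expect_silent(assert_boundaries_simple(b))
    # enclosed areas of exterior boundaries account for all pixels (holes
    # counted inside their enclosing exterior ring)
    lab <- flood_count(m, 8)
    for (bid in b$boundary_id[b$kind == "exterior"]) {
      own <- b$owner[b$boundary_id == bid]
      inner <- sum(b$area[b$kind == "interior" & b$owner == own])
      npix <- sum(lab == own)
      # every anti-crossing shift wedge contributes < 0.02 px^2; count the
      # shifted (off-half-integer) vertices on this component's rings
      rings <- b$points[b$owner == own]
      n_shift <- sum(vapply(rings, function(p) {
        sum(abs(p - round(p - 0.5) - 0.5) > 1e-9) / 2
      }, numeric(1)))
      expect_lt(abs((b$area[b$boundary_id == bid] - inner) - npix),
                0.02 * n_shift + 0.01)
    }
  }
})

test_that("label convention shrinks boundaries a quarter pixel inward", {
  # single-pixel label: square of side 0.5
  m <- matrix(0L, 7, 7); m[4, 4] <- 1L
  b <- trace_label_boundaries(raster_image(m, "label"))
  expect_equal(b$area, 0.25)
  expect_equal(b$perimeter, 2)

  # w x h solid label: area (w - 0.5)(h - 0.5)
  m2 <- matrix(0L, 16, 16); m2[4:9, 3:13] <- 2L
  b2 <- trace_label_boundaries(raster_image(m2, "label"))
  expect_equal(b2$area, (11 - 0.5) * (6 - 0.5))
  expect_equal(b2$owner, 2L)

  # two 4-adjacent labels: disjoint boundaries, facing edges 0.5 px apart
  m3 <- matrix(0L, 9, 9); m3[4:6, 3:4] <- 1L; m3[4:6, 5:6] <- 2L
  b3 <- trace_label_boundaries(raster_image(m3, "label"))
  expect_equal(nrow(b3), 2)
  p1 <- b3$points[[1]]; p2 <- b3$points[[2]]
  expect_equal(max(p1[, 1]), 3.25)   # label 1 pulled back from x = 3.5
  expect_equal(min(p2[, 1]), 3.75)   # label 2 pulled back the other way
  expect_silent(assert_boundaries_simple(b3))

  # largest-4-connected-component rule
  m4 <- matrix(0L, 12, 12)
  m4[3:4, 3:7] <- 1L                 # 10-px component
  m4[8, 3:5] <- 1L                   # 3-px component, same label
  b4 <- trace_label_boundaries(raster_image(m4, "label"))
  expect_equal(nrow(b4), 1)
  expect_equal(b4$area, (5 - 0.5) * (2 - 0.5))

  expect_error(trace_label_boundaries(raster_image(m4, "label"), labels = 0),
               class = "shapegraph_label_error")
  expect_error(trace_label_boundaries(raster_image(m4, "binary")),
               class = "shapegraph_mode_error")
})

test_that("empty foreground yields an empty boundary set", {
  img <- raster_image(matrix(0L, 5, 5), "binary")
  b <- trace_binary_boundaries(img)
  expect_s3_class(b, "shape_boundaries")
  expect_equal(nrow(b), 0)
})
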