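`%||%` <- function(a, b) if (is.null(a)) b else a

fake_cells <- function(n, shiftv = 0, seed = 1) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n * 40), n, 40,
              dimnames = list(NULL, feature_names())) + shiftv
  tibble::as_tibble(x)
}

test_that("well aggregation gives the 76-vector in documented order", {
  cells <- fake_cells(5)
  v <- aggregate_well(cells)
  expect_length(v, 76)
  nm <- names(v)
  expect_equal(sum(startsWith(nm, "mean_")), 38)
  expect_equal(sum(startsWith(nm, "sd_")), 38)
  expect_false(any(grepl("exterior", nm)))
  # means first (in then out), then sds, in Table-1 metric order
  expect_identical(nm[1], "mean_in_width_mean")
  expect_identical(nm[20], "mean_out_width_mean")
  expect_identical(nm[39], "sd_in_width_mean")
  # identical cells: mean = the cell, sds 0
  one <- cells[1, ]
  same <- one[rep(1, 4), ]
  va <- aggregate_well(same)
  expect_equal(unname(va[1:38]),
               as.numeric(one[, shapegraph:::well_metric_names()]))
  expect_equal(unname(va[39:76]), rep(0, 38))
  # symmetry: m and -m average to zero
  pairup <- rbind(one, -one)
  expect_equal(unname(aggregate_well(pairup)[1:38]), rep(0, 38))
  expect_error(aggregate_well(cells[0, ]), class = "shapegraph_empty_error")
})

test_that("aggregation is permutation invariant", {
  cells <- fake_cells(7)
  expect_equal(aggregate_well(cells), aggregate_well(cells[sample(7), ]))
})

test_that("control normalization removes per-plate offsets", {
  set.seed(3)
  wells <- NULL
  layout <- NULL
  for (p in c("P1", "P2")) {
    cf <- fake_cells(40, shiftv = ifelse(p == "P1", 0, 5), seed = 4)
    cf$plate_id <- p
    cf$well_id <- rep(sprintf("w%02d", 1:8), each = 5)
    wells <- rbind(wells, aggregate_wells(cf))
    layout <- rbind(layout, tibble::tibble(
      plate_id = p, well_id = sprintf("w%02d", 1:8),
      class = rep(c("ctrl", "trt"), each = 4),
      is_control = rep(c(TRUE, FALSE), each = 4)))
  }
  norm <- normalize_to_controls(wells, layout)
  fcols <- grep("^(mean|sd)_", colnames(norm), value = TRUE)
  for (p in c("P1", "P2")) {
    ctrl <- norm$plate_id == p & norm$is_control
    med <- apply(norm[ctrl, fcols], 2, median)
    expect_equal(unname(med), rep(0, length(fcols)))
  }
  # translation invariance: shifting one plate leaves its normalized values
  # unchanged and the other plate untouched
  wells2 <- wells
  sel <- wells2$plate_id == "P1"
  wells2[sel, fcols] <- wells2[sel, fcols] + 100
  norm2 <- normalize_to_controls(wells2, layout)
  expect_equal(as.matrix(norm2[, fcols]), as.matrix(norm[, fcols]),
               tolerance = 1e-12)
  # missing controls error
  bad <- layout
  bad$is_control[bad$plate_id == "P2"] <- FALSE
  expect_error(normalize_to_controls(wells, bad),
               class = "shapegraph_config_error")
})

test_that("F1 matches hand-computed values on a toy confusion table", {
  conf <- matrix(c(10, 2, 0,
                   1, 7, 2,
                   0, 1, 9), 3, 3, byrow = TRUE,
                 dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  per <- f1_scores(as.table(conf))
  # class a: precision 10/11, recall 10/12
  expect_equal(per$precision[per$class == "a"], 10 / 11)
  expect_equal(per$recall[per$class == "a"], 10 / 12)
  expect_equal(per$f1[per$class == "a"],
               2 * (10 / 11) * (10 / 12) / (10 / 11 + 10 / 12))
  # the spec's printed example: precision 0.5, recall 1 -> F1 = 2/3
  conf2 <- matrix(c(5, 0, 5, 5), 2, 2, byrow = TRUE,
                  dimnames = list(c("x", "y"), c("x", "y")))
  per2 <- f1_scores(as.table(conf2))
  expect_equal(per2$precision[per2$class == "x"], 0.5)
  expect_equal(per2$recall[per2$class == "x"], 1)
  expect_equal(per2$f1[per2$class == "x"], 2 / 3)
})

test_that("held-out-plate classification separates synthetic classes", {
  set.seed(9)
  wells <- NULL; layout <- NULL
  for (p in paste0("P", 1:4)) {
    for (cl in c("A", "B", "C")) {
      for (w in 1:3) {
        shift <- switch(cl, A = 0, B = 8, C = -8)
        cf <- fake_cells(6, shiftv = shift,
                         seed = length(wells %||% 0) + w * 7)
        cf$plate_id <- p
        cf$well_id <- paste0(cl, w)
        wells <- rbind(wells, aggregate_wells(cf))
        layout <- rbind(layout, tibble::tibble(
          plate_id = p, well_id = paste0(cl, w), class = cl,
          is_control = cl == "A"))
      }
    }
  }
  norm <- normalize_to_controls(wells, layout)
  res <- holdout_plate_classify(norm, seed = 4)
  expect_equal(res$mean_f1, 1)
  expect_equal(sort(res$per_class$class), c("A", "B", "C"))
  # deterministic under fixed seed
  res2 <- holdout_plate_classify(norm, seed = 4)
  expect_identical(res$predictions, res2$predictions)
})

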