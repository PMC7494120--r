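#' Trace object boundaries of a binary image on the half-pixel lattice
#'
#' Boundaries are traced along the half-pixel border separating foreground
#' from background pixels, so a one-pixel-wide line has width exactly 1 and a
#' single pixel encloses area 1. The foreground is 8-connected (background
#' and holes 4-connected). Where the boundary passes twice through the same
#' lattice corner -- two diagonally touching foreground pixels -- the two
#' passes are separated in the off-diagonal direction by `shift` (total
#' distance between the two points, default 1/20 px), so no boundary
#' self-crosses or touches another.
#'
#' @param image a binary [raster_image()].
#' @param shift total anti-crossing separation in pixels.
#' @return A `shape_boundaries` tibble with one row per closed boundary:
#'   `boundary_id`, `kind` (`"exterior"`/`"interior"`), `owner` (foreground
#'   component label), `area` (px^2, enclosed), `perimeter` (px), and a
#'   `points` list column of closed rings (n x 2 matrices, first vertex not
#'   repeated). Exterior rings have positive shoelace orientation.
#' @export
trace_binary_boundaries <- function(image, shift = 0.05) {
  stopifnot(inherits(image, "raster_image"))
  if (image$mode != "binary") {
    abort("trace_binary_boundaries() requires a binary image",
          class = "shapegraph_mode_error")
  }
  v <- image$values
  if (!any(v > 0L)) return(empty_boundaries(image, "binary", shift))
  owners <- label_components(v, conn = 8L)
  loops <- .trace_loops_cpp(v, TRUE)
  rings <- map(loops, function(lp) {
    p <- cbind(lp$x, lp$y)
    k <- shift / (2 * sqrt(2))
    p[, 1] <- p[, 1] + lp$sx * k
    p[, 2] <- p[, 2] + lp$sy * k
    p
  })
  own <- map_int(loops, function(lp) owners[lp$first_r + 1L, lp$first_c + 1L])
  make_boundaries(rings, own, image, "binary", shift)
}

#' Trace per-label boundaries with the quarter-pixel label convention
#'
#' For each label, the largest 4-connected component is traced along the
#' half-pixel border and every boundary point is then moved halfway toward
#' the owning pixel centre (0.25 px inward). One-pixel-wide objects thus
#' have width 0.5 and touching labels are separated by a half-pixel gap, so
#' the background graph threads between contacting cells.
#'
#' @param image a label-mode [raster_image()].
#' @param labels labels to trace (default: all positive labels present).
#' @return A `shape_boundaries` tibble (see [trace_binary_boundaries()]);
#'   `owner` is the label.
#' @export
trace_label_boundaries <- function(image, labels = NULL) {
  stopifnot(inherits(image, "raster_image"))
  if (image$mode != "label") {
    abort("trace_label_boundaries() requires a label image",
          class = "shapegraph_mode_error")
  }
  v <- image$values
  if (is.null(labels)) labels <- sort(unique(v[v > 0L]))
  if (any(labels == 0L)) {
    abort("label 0 is the background, not an object",
          class = "shapegraph_label_error")
  }
  rings <- list(); own <- integer()
  for (lab in labels) {
    mask <- matrix(as.integer(v == lab), nrow = nrow(v))
    if (!any(mask > 0L)) next
    comp <- label_components(mask, conn = 4L)
    sizes <- tabulate(comp, nbins = attr(comp, "n"))
    mask[comp != which.max(sizes)] <- 0L
    loops <- .trace_loops_cpp(mask, FALSE)
    for (lp in loops) {
      p <- cbind(lp$x, lp$y)
      rings[[length(rings) + 1L]] <- offset_ring_inward(p, 0.25)
      own <- c(own, lab)
    }
  }
  if (!length(rings)) return(empty_boundaries(image, "label", 0))
  make_boundaries(rings, own, image, "label", 0)
}

# move each edge of a rectilinear ring toward its left (foreground) side
offset_ring_inward <- function(p, by) {
  n <- nrow(p)
  d <- p[c(2:n, 1L), ] - p                      # edge i: p_i -> p_{i+1}
  l <- cbind(-d[, 2], d[, 1])                   # left normals (unit edges)
  l <- l / sqrt(rowSums(l^2))
  lin <- l[c(n, 1:(n - 1L)), ]                  # incoming edge normal at p_i
  straight <- rowSums(abs(lin - l)) < 1e-9
  q <- p + by * (lin + l)
  q[straight, ] <- p[straight, ] + by * l[straight, ]
  q
}

empty_boundaries <- function(image, convention, shift) {
  make_boundaries(list(), integer(), image, convention, shift)
}

make_boundaries <- function(rings, owners, image, convention, shift) {
  if (length(rings)) {
    area_s <- map_dbl(rings, ring_signed_area)
    b <- tibble(
      boundary_id = seq_along(rings),
      kind = ifelse(area_s > 0, "exterior", "interior"),
      owner = as.integer(owners),
      area = abs(area_s),
      perimeter = map_dbl(rings, ring_perimeter),
      points = rings
    )
  } else {
    b <- tibble(boundary_id = integer(), kind = character(),
                owner = integer(), area = numeric(), perimeter = numeric(),
                points = list())
  }
  structure(b,
            class = c("shape_boundaries", class(b)),
            frame = image_frame(image),
            convention = convention,
            shift = shift,
            image_dim = dim(image$values))
}

ring_signed_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1L)
  sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2]) / 2
}

ring_perimeter <- function(p) {
  n <- nrow(p)
  d <- p[c(2:n, 1L), ] - p
  sum(sqrt(rowSums(d^2)))
}

# cumulative arc position of each ring vertex (first vertex at 0)
ring_arcpos <- function(p) {
  n <- nrow(p)
  d <- p[c(2:n, 1L), ] - p
  c(0, cumsum(sqrt(rowSums(d^2)))[-n])
}

#' Check that no two boundary polylines intersect and none self-crosses
#'
#' Brute-force segment intersection test with a grid prefilter; used by the
#' graph builder to validate inputs and by the test-suite invariants.
#'
#' @param boundaries a `shape_boundaries` tibble.
#' @return `TRUE` invisibly, or an error naming the offending boundary pair.
#' @export
assert_boundaries_simple <- function(boundaries) {
  segs <- boundaries_segments(boundaries)
  if (nrow(segs) < 2) return(invisible(TRUE))
  x1 <- segs$x1; y1 <- segs$y1; x2 <- segs$x2; y2 <- segs$y2
  cell <- 2
  bx0 <- floor(pmin(x1, x2) / cell); bx1 <- floor(pmax(x1, x2) / cell)
  by0 <- floor(pmin(y1, y2) / cell); by1 <- floor(pmax(y1, y2) / cell)
  keys <- vector("list", nrow(segs))
  for (i in seq_len(nrow(segs))) {
    g <- expand.grid(x = bx0[i]:bx1[i], y = by0[i]:by1[i])
    keys[[i]] <- g$x * 100003 + g$y
  }
  buckets <- split(rep(seq_len(nrow(segs)), lengths(keys)), unlist(keys))
  pairs <- unique(do.call(rbind, lapply(buckets, function(ix) {
    if (length(ix) < 2) return(NULL)
    t(utils::combn(sort(ix), 2))
  })))
  if (is.null(pairs) || !nrow(pairs)) return(invisible(TRUE))
  i <- pairs[, 1]; j <- pairs[, 2]
  # skip consecutive segments of the same ring (shared endpoint)
  same_ring <- segs$ring[i] == segs$ring[j]
  consec <- same_ring & (abs(segs$idx[i] - segs$idx[j]) == 1 |
                         abs(segs$idx[i] - segs$idx[j]) == segs$nseg[i] - 1)
  keep <- !consec
  i <- i[keep]; j <- j[keep]
  if (!length(i)) return(invisible(TRUE))
  o1 <- orient(x1[i], y1[i], x2[i], y2[i], x1[j], y1[j])
  o2 <- orient(x1[i], y1[i], x2[i], y2[i], x2[j], y2[j])
  o3 <- orient(x1[j], y1[j], x2[j], y2[j], x1[i], y1[i])
  o4 <- orient(x1[j], y1[j], x2[j], y2[j], x2[i], y2[i])
  bad <- (o1 * o2 < 0 & o3 * o4 < 0) |
    (o1 == 0 & o2 == 0 & o3 == 0 & o4 == 0 &
       pmin(pmax(x1[i], x2[i]), pmax(x1[j], x2[j])) >=
         pmax(pmin(x1[i], x2[i]), pmin(x1[j], x2[j])) &
       pmin(pmax(y1[i], y2[i]), pmax(y1[j], y2[j])) >=
         pmax(pmin(y1[i], y2[i]), pmin(y1[j], y2[j])))
  if (any(bad)) {
    k <- which(bad)[1]
    abort(sprintf("boundaries %d and %d intersect",
                  segs$boundary_id[i[k]], segs$boundary_id[j[k]]),
          class = "shapegraph_geometry_error")
  }
  invisible(TRUE)
}

orient <- function(ax, ay, bx, by, cx, cy) {
  sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
}

# flat table of all ring segments (one row per ring edge)
boundaries_segments <- function(boundaries) {
  if (!nrow(boundaries)) {
    return(tibble(boundary_id = integer(), ring = integer(), idx = integer(),
                  nseg = integer(), x1 = numeric(), y1 = numeric(),
                  x2 = numeric(), y2 = numeric()))
  }
  rows <- pmap(list(boundaries$boundary_id, boundaries$points,
                    seq_len(nrow(boundaries))),
               function(id, p, ring) {
    n <- nrow(p)
    j <- c(2:n, 1L)
    tibble(boundary_id = id, ring = ring, idx = seq_len(n), nseg = n,
           x1 = p[, 1], y1 = p[, 2], x2 = p[j, 1], y2 = p[j, 2])
  })
  list_rbind(rows)
}
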