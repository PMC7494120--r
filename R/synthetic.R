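#' Synthetic raster primitives with known ground truth
#'
#' Rasterizes simple shapes with analytically known area, inradius, and
#' protrusion length, for testing every pipeline stage without external
#' data. A pixel is foreground when its centre lies inside the shape.
#'
#' * `disk`: radius `r` at `centre`.
#' * `annulus`: outer radius `r`, inner radius `r_inner`.
#' * `bar`: axis-aligned `width` x `height` rectangle of pixels.
#' * `spiked_disk`: disk of radius `r` with a one-pixel-wide horizontal
#'   spike of length `spike` protruding to the right.
#'
#' @param kind shape kind.
#' @param size image size in pixels (square, `size x size`).
#' @param r radius (disks/annuli), px.
#' @param r_inner inner radius for `annulus`.
#' @param width,height bar dimensions in pixels.
#' @param spike spike length in pixels for `spiked_disk`.
#' @param centre shape centre in pixel coordinates (default image centre).
#' @return A binary [raster_image()].
#' @export
make_primitive <- function(kind = c("disk", "annulus", "bar", "spiked_disk"),
                           size = 128, r = 25, r_inner = 15,
                           width = 40, height = 10, spike = 10,
                           centre = c((size - 1) / 2, (size - 1) / 2)) {
  kind <- match.arg(kind)
  cx <- centre[1]; cy <- centre[2]
  xs <- matrix(rep(0:(size - 1), each = size), nrow = size)   # x = col - 1
  ys <- matrix(rep(0:(size - 1), times = size), nrow = size)  # y = row - 1
  d2 <- (xs - cx)^2 + (ys - cy)^2
  m <- switch(kind,
    disk = d2 <= r^2,
    annulus = d2 <= r^2 & d2 >= r_inner^2,
    bar = {
      x0 <- round(cx - (width - 1) / 2); y0 <- round(cy - (height - 1) / 2)
      xs >= x0 & xs <= x0 + width - 1 & ys >= y0 & ys <= y0 + height - 1
    },
    spiked_disk = d2 <= r^2 |
      (abs(ys - round(cy)) < 0.5 & xs > cx & xs <= cx + r + spike)
  )
  check_margin(m, kind)
  raster_image(matrix(as.integer(m), nrow = size), "binary")
}

check_margin <- function(m, what) {
  if (any(m[1, ]) || any(m[nrow(m), ]) || any(m[, 1]) || any(m[, ncol(m)])) {
    abort(sprintf("%s geometry does not fit the frame", what),
          class = "shapegraph_geometry_error")
  }
}

#' Mesh-network generator (phenomenological)
#'
#' Generates a random mesh of blobs and struts emulating multicellular
#' network images: `n_seeds` points are scattered (with a minimum spacing),
#' neighbouring pairs are connected independently with probability
#' `connectivity`, and each connection is drawn as a strut of half-width
#' `density`; seed blobs of radius `density + 1.5` are added. Expected
#' hole count grows with `connectivity` and the mean foreground width grows
#' with `density`. A 2-px clear margin is enforced at the frame.
#'
#' This is a stand-in for mechanistic cell simulations: it guarantees the
#' monotone structure/parameter relationships, nothing more.
#'
#' @param connectivity probability in `[0, 1]` of joining a neighbour pair.
#' @param density strut half-width scale, px (> 0).
#' @param n_seeds number of scattered seeds.
#' @param size image size, px.
#' @param seed RNG seed.
#' @return A binary [raster_image()] with attribute `"params"` =
#'   `c(connectivity, density)` and `"n_struts"`.
#' @export
make_mesh <- function(connectivity = 0.5, density = 2, n_seeds = 40,
                      size = 160, seed = 1) {
  stopifnot(connectivity >= 0, connectivity <= 1, density > 0)
  set.seed(seed)
  margin <- 2 + ceiling(density + 1.5)
  lo <- margin; hi <- size - 1 - margin
  # scatter with rejection for minimum spacing
  min_d <- (hi - lo) / (sqrt(n_seeds) * 1.6)
  px <- numeric(0); py <- numeric(0)
  tries <- 0
  while (length(px) < n_seeds && tries < 4000) {
    tries <- tries + 1
    x <- stats::runif(1, lo, hi); y <- stats::runif(1, lo, hi)
    if (!length(px) || min(sqrt((px - x)^2 + (py - y)^2)) >= min_d) {
      px <- c(px, x); py <- c(py, y)
    }
  }
  n <- length(px)
  dm <- as.matrix(dist(cbind(px, py)))
  thr <- 3.0 * stats::median(apply(dm + diag(Inf, n), 1, min))
  pairs <- which(upper.tri(dm) & dm < thr, arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < connectivity
  pairs <- pairs[keep, , drop = FALSE]
  xs <- matrix(rep(0:(size - 1), each = size), nrow = size)
  ys <- matrix(rep(0:(size - 1), times = size), nrow = size)
  m <- matrix(FALSE, size, size)
  rblob <- density + 1.5
  for (i in seq_len(n)) {
    m <- m | ((xs - px[i])^2 + (ys - py[i])^2 <= rblob^2)
  }
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    m <- m | (seg_dist2(xs, ys, px[i], py[i], px[j], py[j]) <= density^2)
  }
  m[1:2, ] <- FALSE; m[(size - 1):size, ] <- FALSE
  m[, 1:2] <- FALSE; m[, (size - 1):size] <- FALSE
  out <- raster_image(matrix(as.integer(m), nrow = size), "binary")
  attr(out, "params") <- c(connectivity = connectivity, density = density)
  attr(out, "n_struts") <- nrow(pairs)
  out
}

# squared distance from grid points to segment (x1,y1)-(x2,y2)
seg_dist2 <- function(xs, ys, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  L2 <- dx^2 + dy^2
  t <- pmin(pmax(((xs - x1) * dx + (ys - y1) * dy) / L2, 0), 1)
  (xs - (x1 + t * dx))^2 + (ys - (y1 + t * dy))^2
}

#' Label mosaic generator
#'
#' A space-filling tessellation: each pixel takes the label of its nearest
#' seed point, emulating tightly packed segmented cells for the label-image
#' tracing convention (adjacent cells' traced boundaries end up 0.5 px
#' apart).
#'
#' @param n_cells number of labels.
#' @param size image size, px.
#' @param seed RNG seed.
#' @return A label-mode [raster_image()]; attribute `"adjacency"` is a
#'   two-column matrix of 4-adjacent label pairs.
#' @export
make_label_mosaic <- function(n_cells = 8, size = 64, seed = 1) {
  stopifnot(n_cells >= 1)
  set.seed(seed)
  px <- stats::runif(n_cells, 0, size - 1)
  py <- stats::runif(n_cells, 0, size - 1)
  xs <- matrix(rep(0:(size - 1), each = size), nrow = size)
  ys <- matrix(rep(0:(size - 1), times = size), nrow = size)
  lab <- matrix(0L, size, size)
  best <- matrix(Inf, size, size)
  for (i in seq_len(n_cells)) {
    d2 <- (xs - px[i])^2 + (ys - py[i])^2
    upd <- d2 < best
    lab[upd] <- i
    best[upd] <- d2[upd]
  }
  adj <- unique(rbind(
    cbind(as.vector(lab[-nrow(lab), ]), as.vector(lab[-1, ])),
    cbind(as.vector(lab[, -ncol(lab)]), as.vector(lab[, -1]))
  ))
  adj <- adj[adj[, 1] != adj[, 2], , drop = FALSE]
  adj <- unique(t(apply(adj, 1, sort)))
  out <- raster_image(lab, "label")
  attr(out, "adjacency") <- adj
  out
}
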