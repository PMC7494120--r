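# shared fixtures and independent oracles for the test suite

# cache for expensive fixtures reused across test files
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# independent connected-component count (plain R flood fill, not the
# package's C++ labelling)
flood_count <- function(mask, conn = 8) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  dr <- if (conn == 8) c(-1, 1, 0, 0, -1, -1, 1, 1) else c(-1, 1, 0, 0)
  dc <- if (conn == 8) c(0, 0, -1, 1, -1, 1, -1, 1) else c(0, 0, -1, 1)
  for (c0 in seq_len(W)) for (r0 in seq_len(H)) {
    if (mask[r0, c0] == 0 || lab[r0, c0] != 0) next
    nxt <- nxt + 1L
    stack <- list(c(r0, c0))
    lab[r0, c0] <- nxt
    while (length(stack)) {
      rc <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_along(dr)) {
        rr <- rc[1] + dr[k]; cc <- rc[2] + dc[k]
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= W &&
            mask[rr, cc] != 0 && lab[rr, cc] == 0) {
          lab[rr, cc] <- nxt
          stack[[length(stack) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  attr(lab, "n") <- nxt
  lab
}

# holes: 4-connected background components not touching the border
hole_count <- function(mask) {
  bg <- flood_count(1L - mask, conn = 4)
  n <- attr(bg, "n")
  if (n == 0) return(0L)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  length(setdiff(seq_len(n), c(0L, border)))
}

# distance from points to the nearest background pixel centre, minus the
# half-pixel border offset: an independent proxy for foreground clearance
bg_clearance_at <- function(image, x, y) {
  v <- image$values
  bgpix <- which(v == 0L, arr.ind = TRUE)
  bx <- bgpix[, 2] - 1; by <- bgpix[, 1] - 1
  vapply(seq_along(x), function(i) {
    sqrt(min((bx - x[i])^2 + (by - y[i])^2)) - 0.5
  }, numeric(1))
}

# exact Euclidean distance transform values (to nearest bg pixel centre)
# for all foreground pixels; returns max location and value
dt_max <- function(image) {
  v <- image$values
  fg <- which(v != 0L, arr.ind = TRUE)
  bgpix <- which(v == 0L, arr.ind = TRUE)
  bx <- bgpix[, 2] - 1; by <- bgpix[, 1] - 1
  best <- -Inf; bestxy <- c(NA, NA)
  for (i in seq_len(nrow(fg))) {
    x <- fg[i, 2] - 1; y <- fg[i, 1] - 1
    d <- sqrt(min((bx - x)^2 + (by - y)^2))
    if (d > best) { best <- d; bestxy <- c(x, y) }
  }
  list(value = best - 0.5, x = bestxy[1], y = bestxy[2])
}

# seeded random non-crossing segment instances (each segment's endpoints are
# point sites), for oracle-equivalence checks
random_segment_sites <- function(n_seg, seed, box = 40) {
  set.seed(seed)
  segs <- matrix(numeric(0), 0, 4)
  crosses <- function(s, t) {
    o <- function(ax, ay, bx, by, px, py) {
      sign((bx - ax) * (py - ay) - (by - ay) * (px - ax))
    }
    o1 <- o(s[1], s[2], s[3], s[4], t[1], t[2])
    o2 <- o(s[1], s[2], s[3], s[4], t[3], t[4])
    o3 <- o(t[1], t[2], t[3], t[4], s[1], s[2])
    o4 <- o(t[1], t[2], t[3], t[4], s[3], s[4])
    o1 * o2 < 0 && o3 * o4 < 0
  }
  tries <- 0
  while (nrow(segs) < n_seg && tries < 800) {
    tries <- tries + 1
    a <- stats::runif(2, 3, box - 3)
    ang <- stats::runif(1, 0, 2 * pi)
    len <- stats::runif(1, 2, 8)
    b <- a + len * c(cos(ang), sin(ang))
    if (any(b < 3) || any(b > box - 3)) next
    cand <- c(a, b)
    if (nrow(segs) && any(apply(segs, 1, crosses, t = cand))) next
    P <- rbind(segs[, 1:2, drop = FALSE], segs[, 3:4, drop = FALSE])
    if (nrow(P) && min(sqrt((P[, 1] - a[1])^2 + (P[, 2] - a[2])^2),
                       sqrt((P[, 1] - b[1])^2 + (P[, 2] - b[2])^2)) < 0.5) {
      next
    }
    segs <- rbind(segs, cand)
  }
  n <- nrow(segs)
  list(points = rbind(segs[, 1:2, drop = FALSE], segs[, 3:4, drop = FALSE]),
       segments = segs, p1 = seq_len(n), p2 = n + seq_len(n),
       frame = c(0, 0, box, box))
}

# compare two shape graphs as vertex multisets (positions + clearances)
expect_same_vertices <- function(g1, g2, tol = 1e-6) {
  v1 <- g1$vertices[!duplicated(round(cbind(g1$vertices$x, g1$vertices$y),
                                     9)), ]
  v2 <- g2$vertices[!duplicated(round(cbind(g2$vertices$x, g2$vertices$y),
                                     9)), ]
  expect_equal(nrow(v1), nrow(v2))
  o1 <- order(round(v1$x, 6), round(v1$y, 6))
  o2 <- order(round(v2$x, 6), round(v2$y, 6))
  expect_lt(max(abs(v1$x[o1] - v2$x[o2]), abs(v1$y[o1] - v2$y[o2]),
                abs(v1$clearance[o1] - v2$clearance[o2])), tol)
}

# the seeded 100-image mesh sweep shared by the acceptance tests
mesh_sweep <- function() {
  cached("mesh_sweep", {
    conn <- seq(0.05, 0.95, length.out = 10)
    dens <- seq(1.0, 2.6, length.out = 10)
    grid <- expand.grid(connectivity = conn, density = dens)
    imgs <- list()
    for (i in seq_len(nrow(grid))) {
      imgs[[sprintf("img%03d", i)]] <- make_mesh(
        grid$connectivity[i], grid$density[i],
        n_seeds = 50, size = 144, seed = 1000 + i)
    }
    feats <- extract_features_set(imgs)
    list(grid = grid, features = feats)
  })
}

sweep_histograms <- function(sw, use_features = feature_names()) {
  model <- fit_boundary_types(sw$features, n_types = 12, seed = 7,
                              use_features = use_features)
  h <- image_histograms(model, sw$features)
  h[match(sprintf("img%03d", seq_len(nrow(sw$grid))), h$image_id), ]
}
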