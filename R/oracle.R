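#' Brute-force tangent-circle oracle for the shape graph
#'
#' Reconstructs the generalized Voronoi diagram by exhaustive enumeration:
#' for every triple of sites all circles tangent to the three are found in
#' closed form (circumcircle; circle through two points tangent to a line;
#' through one point tangent to two lines; tritangent circles of three
#' lines), candidates whose tangency feet fall off their segments or that
#' contain another site are discarded, and coincident solutions are merged.
#' Cubic cost -- for verification only, capped at `cap` sites.
#'
#' @param boundaries a `shape_boundaries` tibble.
#' @param frame bounding rectangle (default: the image frame).
#' @param cap maximum number of sites (error above this).
#' @return A `shape_graph` with vertices, tangents, and edges.
#' @export
oracle_graph <- function(boundaries, frame = attr(boundaries, "frame"),
                         cap = 200) {
  sites <- boundary_sites(boundaries, frame)
  g <- oracle_of_sites(sites, cap = cap)
  g$boundaries <- boundaries
  g$frame <- frame
  g
}

#' Oracle diagram of explicit sites
#'
#' @param sites a site table as built by [voronoi_diagram()] internals, or
#'   pass `points`/`segments` through [voronoi_diagram()]'s conventions.
#' @param cap maximum site count.
#' @param tol tangency/emptiness tolerance, px.
#' @return A `shape_graph` (no `boundaries`).
#' @export
oracle_of_sites <- function(sites, cap = 200, tol = 1e-7) {
  n <- nrow(sites)
  if (n > cap) {
    abort(sprintf("oracle capped at %d sites (got %d)", cap, n),
          class = "shapegraph_size_error")
  }
  is_pt <- sites$type == "point"
  cand <- oracle_candidates(sites)
  if (!nrow(cand)) {
    return(structure(list(
      vertices = tibble(vertex_id = integer(), x = numeric(), y = numeric(),
                        clearance = numeric()),
      edges = tibble(edge_id = integer(), v1 = integer(), v2 = integer(),
                     site1 = integer(), site2 = integer(),
                     curve_kind = character(), length = numeric()),
      tangents = tibble(vertex_id = integer(), site_id = integer(),
                        tx = numeric(), ty = numeric()),
      sites = sites, frame = NULL, boundaries = NULL),
      class = "shape_graph"))
  }
  # loose pre-filter, Newton polish, then the tight tangency filter
  d1 <- oracle_dvalid(sites, cand$s1, cand$x, cand$y)
  d2 <- oracle_dvalid(sites, cand$s2, cand$x, cand$y)
  d3 <- oracle_dvalid(sites, cand$s3, cand$x, cand$y)
  r0 <- (d1 + d2 + d3) / 3
  ok <- is.finite(d1) & is.finite(d2) & is.finite(d3) &
    pmax(abs(d1 - r0), abs(d2 - r0), abs(d3 - r0)) <= 1e-4 * pmax(1, r0)
  cand <- cand[ok, ]
  if (nrow(cand)) {
    for (k in seq_len(nrow(cand))) {
      xy <- oracle_polish(sites, cand$s1[k], cand$s2[k], cand$s3[k],
                          cand$x[k], cand$y[k])
      cand$x[k] <- xy[1]; cand$y[k] <- xy[2]
    }
  }
  d1 <- oracle_dvalid(sites, cand$s1, cand$x, cand$y)
  d2 <- oracle_dvalid(sites, cand$s2, cand$x, cand$y)
  d3 <- oracle_dvalid(sites, cand$s3, cand$x, cand$y)
  r <- (d1 + d2 + d3) / 3
  ok <- is.finite(d1) & is.finite(d2) & is.finite(d3) &
    pmax(abs(d1 - r), abs(d2 - r), abs(d3 - r)) <= tol * pmax(1, r)
  cand <- cand[ok, ]; r <- r[ok]
  # emptiness against all sites (closed distance)
  if (nrow(cand)) {
    keep <- rep(TRUE, nrow(cand))
    for (j in seq_len(n)) {
      dj <- oracle_dclosed(sites, j, cand$x, cand$y)
      keep <- keep & (dj >= r - tol * pmax(1, r))
    }
    cand <- cand[keep, ]; r <- r[keep]
  }
  if (!nrow(cand)) abort("oracle found no vertices")
  # merge coincident candidates (cluster within 1e-6, not bin rounding)
  o <- order(cand$x, cand$y)
  cand <- cand[o, ]; r <- r[o]
  keep <- rep(TRUE, nrow(cand))
  kept_x <- numeric(0); kept_y <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    if (length(kept_x)) {
      near <- which(abs(kept_x - cand$x[i]) <= 1e-6)
      if (length(near) && any(abs(kept_y[near] - cand$y[i]) <= 1e-6 &
                                sqrt((kept_x[near] - cand$x[i])^2 +
                                       (kept_y[near] - cand$y[i])^2) <= 1e-6)) {
        keep[i] <- FALSE
        next
      }
    }
    kept_x <- c(kept_x, cand$x[i]); kept_y <- c(kept_y, cand$y[i])
  }
  vx <- cand$x[keep]; vy <- cand$y[keep]; vr <- r[keep]
  # full tangent sets per vertex, perturbed-angle ordered
  tang <- vector("list", length(vx))
  for (v in seq_along(vx)) {
    dv <- oracle_dvalid(sites, seq_len(n), vx[v], vy[v])
    ts <- which(is.finite(dv) & abs(dv - vr[v]) <= tol * max(1, vr[v]))
    ft <- oracle_feet(sites, ts, vx[v], vy[v])
    ang <- oracle_angles(sites, ts, vx[v], vy[v], ft)
    o <- order(ang)
    tang[[v]] <- tibble(vertex = v, site = ts[o],
                        tx = ft[o, 1], ty = ft[o, 2])
  }
  tang <- list_rbind(tang)
  edges <- oracle_edges(sites, vx, vy, vr, tang, tol)
  res <- list(vx = vx, vy = vy, vr = vr,
              tang_vertex = tang$vertex, tang_site = tang$site,
              tang_x = tang$tx, tang_y = tang$ty,
              e_v1 = edges$v1, e_v2 = edges$v2,
              e_s1 = edges$s1, e_s2 = edges$s2,
              e_kind = edges$kind, e_len = edges$len)
  g <- split_degenerate_vertices(res, 1e-6)
  structure(list(vertices = g$vertices, edges = g$edges,
                 tangents = g$tangents, sites = sites,
                 frame = NULL, boundaries = NULL),
            class = "shape_graph")
}

# ---- candidate centres by closed form ------------------------------------

oracle_candidates <- function(sites) {
  n <- nrow(sites)
  tr <- t(utils::combn(n, 3))
  is_pt <- sites$type == "point"
  npts <- is_pt[tr[, 1]] + is_pt[tr[, 2]] + is_pt[tr[, 3]]
  out <- list()
  emit <- function(s1, s2, s3, x, y) {
    ok <- is.finite(x) & is.finite(y)
    if (any(ok)) {
      out[[length(out) + 1L]] <<- tibble(s1 = s1[ok], s2 = s2[ok],
                                         s3 = s3[ok], x = x[ok], y = y[ok])
    }
  }
  # --- three points: circumcentre
  t3 <- tr[npts == 3L, , drop = FALSE]
  if (nrow(t3)) {
    ax <- sites$x[t3[, 1]]; ay <- sites$y[t3[, 1]]
    bx <- sites$x[t3[, 2]]; by <- sites$y[t3[, 2]]
    cx <- sites$x[t3[, 3]]; cy <- sites$y[t3[, 3]]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    bad <- abs(d) < 1e-12
    ux[bad] <- NA; uy[bad] <- NA
    emit(t3[, 1], t3[, 2], t3[, 3], ux, uy)
  }
  # --- two points + one segment
  t2 <- tr[npts == 2L, , drop = FALSE]
  if (nrow(t2)) {
    sp <- t(apply(t2, 1, function(z) c(z[is_pt[z]], z[!is_pt[z]])))
    p1 <- sp[, 1]; p2 <- sp[, 2]; sg <- sp[, 3]
    mx <- (sites$x[p1] + sites$x[p2]) / 2
    my <- (sites$y[p1] + sites$y[p2]) / 2
    dx <- sites$x[p2] - sites$x[p1]; dy <- sites$y[p2] - sites$y[p1]
    L <- sqrt(dx^2 + dy^2)
    wx <- -dy / L; wy <- dx / L
    h <- L / 2
    ux <- sites$x2[sg] - sites$x1[sg]; uy <- sites$y2[sg] - sites$y1[sg]
    ul <- sqrt(ux^2 + uy^2); ux <- ux / ul; uy <- uy / ul
    e <- ux * (my - sites$y1[sg]) - uy * (mx - sites$x1[sg])  # cross(u, m - a)
    f <- ux * wy - uy * wx
    qa <- 1 - f^2; qb <- -2 * e * f; qc <- h^2 - e^2
    rt <- solve_quad(qa, qb, qc)
    for (k in 1:2) {
      t <- rt[, k]
      emit(p1, p2, sg, mx + t * wx, my + t * wy)
    }
    # spoke family: a point lying on the segment's line (its endpoint) has
    # its tangent circles centred on the perpendicular at that point
    for (swap in 1:2) {
      pa <- if (swap == 1) p1 else p2
      pb <- if (swap == 1) p2 else p1
      eon <- ux * (sites$y[pa] - sites$y1[sg]) -
        uy * (sites$x[pa] - sites$x1[sg])
      on <- which(abs(eon) < 1e-9)
      if (length(on)) {
        nx <- -uy[on]; ny <- ux[on]
        ddx <- sites$x[pa][on] - sites$x[pb][on]
        ddy <- sites$y[pa][on] - sites$y[pb][on]
        den <- 2 * (nx * ddx + ny * ddy)
        t <- ifelse(abs(den) > 1e-12, -(ddx^2 + ddy^2) / den, NA)
        emit(p1[on], p2[on], sg[on],
             sites$x[pa][on] + t * nx, sites$y[pa][on] + t * ny)
      }
    }
  }
  # --- one point + two segments
  t1 <- tr[npts == 1L, , drop = FALSE]
  if (nrow(t1)) {
    sp <- t(apply(t1, 1, function(z) c(z[is_pt[z]], z[!is_pt[z]])))
    pp <- sp[, 1]; g1 <- sp[, 2]; g2 <- sp[, 3]
    u1x <- sites$x2[g1] - sites$x1[g1]; u1y <- sites$y2[g1] - sites$y1[g1]
    l1 <- sqrt(u1x^2 + u1y^2); u1x <- u1x / l1; u1y <- u1y / l1
    u2x <- sites$x2[g2] - sites$x1[g2]; u2y <- sites$y2[g2] - sites$y1[g2]
    l2 <- sqrt(u2x^2 + u2y^2); u2x <- u2x / l2; u2y <- u2y / l2
    cr <- u1x * u2y - u1y * u2x
    par <- abs(cr) < 1e-12
    # non-parallel: intersection point o, branch dirs u1 +/- u2
    ix <- which(!par)
    if (length(ix)) {
      # solve a1 + s u1 = a2 + t u2
      s <- ((sites$x1[g2] - sites$x1[g1]) * u2y -
              (sites$y1[g2] - sites$y1[g1]) * u2x)[ix] / cr[ix]
      ox <- sites$x1[g1][ix] + s * u1x[ix]
      oy <- sites$y1[g1][ix] + s * u1y[ix]
      for (sgn in c(1, -1)) {
        wx <- u1x[ix] + sgn * u2x[ix]; wy <- u1y[ix] + sgn * u2y[ix]
        wl <- sqrt(wx^2 + wy^2)
        wx <- wx / wl; wy <- wy / wl
        kk <- abs(wx * u1y[ix] - wy * u1x[ix])  # |cross(w, u1)|
        px <- sites$x[pp][ix]; py <- sites$y[pp][ix]
        qa <- 1 - kk^2
        qb <- 2 * (wx * (ox - px) + wy * (oy - py))
        qc <- (ox - px)^2 + (oy - py)^2
        rt <- solve_quad(qa, qb, qc)
        for (k in 1:2) {
          t <- rt[, k]
          emit(pp[ix], g1[ix], g2[ix], ox + t * wx, oy + t * wy)
        }
      }
    }
    # spoke family: the point lies on one of the lines (segment endpoint)
    for (swap in 1:2) {
      gux <- if (swap == 1) u1x else u2x
      guy <- if (swap == 1) u1y else u2y
      gax <- if (swap == 1) sites$x1[g1] else sites$x1[g2]
      gay <- if (swap == 1) sites$y1[g1] else sites$y1[g2]
      oux <- if (swap == 1) u2x else u1x
      ouy <- if (swap == 1) u2y else u1y
      oax <- if (swap == 1) sites$x1[g2] else sites$x1[g1]
      oay <- if (swap == 1) sites$y1[g2] else sites$y1[g1]
      eon <- gux * (sites$y[pp] - gay) - guy * (sites$x[pp] - gax)
      on <- which(abs(eon) < 1e-9)
      if (length(on)) {
        nx <- -guy[on]; ny <- gux[on]
        n2x <- -ouy[on]; n2y <- oux[on]
        bb <- n2x * (sites$x[pp][on] - oax[on]) +
          n2y * (sites$y[pp][on] - oay[on])
        aa <- n2x * nx + n2y * ny
        for (sgn in c(1, -1)) {
          den <- sgn - aa
          t <- ifelse(abs(den) > 1e-12, bb / den, NA)
          emit(pp[on], g1[on], g2[on],
               sites$x[pp][on] + t * nx, sites$y[pp][on] + t * ny)
        }
      }
    }
    ix <- which(par)
    if (length(ix)) {
      # midline between the two parallel lines
      sgn2 <- sign((sites$x1[g2] - sites$x1[g1]) * (-u1y) +
                     (sites$y1[g2] - sites$y1[g1]) * u1x)[ix]
      gap <- abs(((sites$x1[g2] - sites$x1[g1]) * (-u1y) +
                    (sites$y1[g2] - sites$y1[g1]) * u1x))[ix]
      m0x <- sites$x1[g1][ix] + (-u1y[ix]) * sgn2 * gap / 2
      m0y <- sites$y1[g1][ix] + u1x[ix] * sgn2 * gap / 2
      px <- sites$x[pp][ix]; py <- sites$y[pp][ix]
      h <- gap / 2
      qa <- rep(1, length(ix))
      qb <- -2 * ((px - m0x) * u1x[ix] + (py - m0y) * u1y[ix])
      qc <- (px - m0x)^2 + (py - m0y)^2 - h^2
      rt <- solve_quad(qa, qb, qc)
      for (k in 1:2) {
        t <- rt[, k]
        emit(pp[ix], g1[ix], g2[ix], m0x + t * u1x[ix], m0y + t * u1y[ix])
      }
    }
  }
  # --- three segments: sign-combination linear solves
  t0 <- tr[npts == 0L, , drop = FALSE]
  if (nrow(t0)) {
    nx <- list(); ny <- list(); dd <- list()
    for (k in 1:3) {
      g <- t0[, k]
      ux <- sites$x2[g] - sites$x1[g]; uy <- sites$y2[g] - sites$y1[g]
      l <- sqrt(ux^2 + uy^2)
      nx[[k]] <- -uy / l; ny[[k]] <- ux / l
      dd[[k]] <- nx[[k]] * sites$x1[g] + ny[[k]] * sites$y1[g]
    }
    for (s2 in c(1, -1)) for (s3 in c(1, -1)) {
      a11 <- nx[[1]] - s2 * nx[[2]]; a12 <- ny[[1]] - s2 * ny[[2]]
      a21 <- nx[[1]] - s3 * nx[[3]]; a22 <- ny[[1]] - s3 * ny[[3]]
      b1 <- dd[[1]] - s2 * dd[[2]]; b2 <- dd[[1]] - s3 * dd[[3]]
      det <- a11 * a22 - a12 * a21
      x <- (b1 * a22 - b2 * a12) / det
      y <- (a11 * b2 - a21 * b1) / det
      x[abs(det) < 1e-12] <- NA
      emit(t0[, 1], t0[, 2], t0[, 3], x, y)
    }
  }
  if (!length(out)) {
    return(tibble(s1 = integer(), s2 = integer(), s3 = integer(),
                  x = numeric(), y = numeric()))
  }
  list_rbind(out)
}

solve_quad <- function(a, b, cc) {
  lin <- abs(a) < 1e-13
  disc <- b^2 - 4 * a * cc
  # double roots (e.g. spoke vertices, where a point site lies on a
  # segment's line) sit at disc = 0 and may compute slightly negative
  scale <- b^2 + abs(4 * a * cc)
  disc[disc < 0 & disc > -1e-9 * scale] <- 0
  sq <- sqrt(pmax(disc, 0))
  r1 <- (-b - sq) / (2 * a)
  r2 <- (-b + sq) / (2 * a)
  r1[disc < 0] <- NA; r2[disc < 0] <- NA
  r1[lin] <- ifelse(abs(b[lin]) > 1e-13, -cc[lin] / b[lin], NA)
  r2[lin] <- NA
  cbind(r1, r2)
}

# Newton refinement of a candidate centre toward d(s1) = d(s2) = d(s3),
# using closed-foot gradients (unit vectors from foot to centre)
oracle_polish <- function(sites, s1, s2, s3, x, y) {
  tri <- c(s1, s2, s3)
  for (it in 1:25) {
    d <- numeric(3); fx <- numeric(3); fy <- numeric(3)
    for (k in 1:3) {
      ft <- site_foot(sites[tri[k], ], x, y)
      fx[k] <- ft[1]; fy[k] <- ft[2]
      d[k] <- sqrt((x - ft[1])^2 + (y - ft[2])^2)
    }
    if (any(d < 1e-12)) break
    g1 <- c((x - fx[1]) / d[1] - (x - fx[3]) / d[3],
            (y - fy[1]) / d[1] - (y - fy[3]) / d[3])
    g2 <- c((x - fx[2]) / d[2] - (x - fx[3]) / d[3],
            (y - fy[2]) / d[2] - (y - fy[3]) / d[3])
    F <- c(d[1] - d[3], d[2] - d[3])
    det <- g1[1] * g2[2] - g1[2] * g2[1]
    if (abs(det) < 1e-14) break
    dx <- (F[1] * g2[2] - F[2] * g1[2]) / det
    dy <- (g1[1] * F[2] - g2[1] * F[1]) / det
    x <- x - dx; y <- y - dy
    if (abs(dx) + abs(dy) < 1e-14) break
  }
  c(x, y)
}

# valid (foot-restricted) distance from (x, y) to site j (vectorized over j
# or over points)
oracle_dvalid <- function(sites, j, x, y) {
  tp <- sites$type[j]
  d <- rep(NA_real_, max(length(j), length(x)))
  pt <- tp == "point"
  if (any(pt)) {
    jj <- j[pt]
    d[pt] <- sqrt((rep(x, length.out = length(j))[pt] - sites$x[jj])^2 +
                    (rep(y, length.out = length(j))[pt] - sites$y[jj])^2)
  }
  sg <- !pt
  if (any(sg)) {
    jj <- j[sg]
    xx <- rep(x, length.out = length(j))[sg]
    yy <- rep(y, length.out = length(j))[sg]
    ux <- sites$x2[jj] - sites$x1[jj]; uy <- sites$y2[jj] - sites$y1[jj]
    l <- sqrt(ux^2 + uy^2); ux <- ux / l; uy <- uy / l
    t <- (xx - sites$x1[jj]) * ux + (yy - sites$y1[jj]) * uy
    perp <- abs(ux * (yy - sites$y1[jj]) - uy * (xx - sites$x1[jj]))
    perp[t < -1e-7 | t > l + 1e-7] <- NA
    d[sg] <- perp
  }
  d
}

# closed distance from candidate points to one site j (vectorized over x, y)
oracle_dclosed <- function(sites, j, x, y) {
  if (sites$type[j] == "point") {
    sqrt((x - sites$x[j])^2 + (y - sites$y[j])^2)
  } else {
    ux <- sites$x2[j] - sites$x1[j]; uy <- sites$y2[j] - sites$y1[j]
    l <- sqrt(ux^2 + uy^2); ux <- ux / l; uy <- uy / l
    t <- pmin(pmax((x - sites$x1[j]) * ux + (y - sites$y1[j]) * uy, 0), l)
    sqrt((x - (sites$x1[j] + t * ux))^2 + (y - (sites$y1[j] + t * uy))^2)
  }
}

oracle_feet <- function(sites, j, x, y) {
  ft <- matrix(NA_real_, length(j), 2)
  for (k in seq_along(j)) {
    s <- sites[j[k], ]
    ft[k, ] <- site_foot(s, x, y)
  }
  ft
}

# tangency angles with the endpoint-coincidence perturbation (a segment
# tangent at its own endpoint is ordered on the side of its body)
oracle_angles <- function(sites, j, x, y, ft) {
  ang <- atan2(ft[, 2] - y, ft[, 1] - x)
  for (k in seq_along(j)) {
    s <- sites[j[k], ]
    if (s$type != "segment") next
    ux <- s$x2 - s$x1; uy <- s$y2 - s$y1
    l <- sqrt(ux^2 + uy^2); ux <- ux / l; uy <- uy / l
    bx <- by <- 0
    if (sqrt((ft[k, 1] - s$x1)^2 + (ft[k, 2] - s$y1)^2) < 1e-7) {
      bx <- ux; by <- uy
    } else if (sqrt((ft[k, 1] - s$x2)^2 + (ft[k, 2] - s$y2)^2) < 1e-7) {
      bx <- -ux; by <- -uy
    }
    if (bx != 0 || by != 0) {
      cr <- (ft[k, 1] - x) * by - (ft[k, 2] - y) * bx
      ang[k] <- ang[k] + ifelse(cr > 0, 1e-6, -1e-6)
    }
  }
  ang
}

# edges: for each site pair, order common vertices along the bisector and
# keep consecutive links whose curve midpoint is still empty
oracle_edges <- function(sites, vx, vy, vr, tang, tol) {
  n <- nrow(sites)
  out <- list(v1 = integer(), v2 = integer(), s1 = integer(),
              s2 = integer(), kind = integer(), len = numeric())
  by_v <- split(tang$site, tang$vertex)
  pairs <- list()
  for (v in names(by_v)) {
    ts <- by_v[[v]]
    k <- length(ts)
    if (k < 2) next
    ts_ord <- ts  # already angular order
    pr <- cbind(ts_ord, ts_ord[c(2:k, 1)])
    pairs[[v]] <- pr
  }
  allp <- unique(t(apply(do.call(rbind, pairs), 1, sort)))
  for (q in seq_len(nrow(allp))) {
    a <- allp[q, 1]; b <- allp[q, 2]
    vs <- intersect(tang$vertex[tang$site == a], tang$vertex[tang$site == b])
    if (length(vs) < 2) next
    pm <- oracle_bisector_param(sites, a, b, vx[vs], vy[vs])
    for (br in unique(pm$branch)) {
      ix <- which(pm$branch == br)
      if (length(ix) < 2) next
      o <- ix[order(pm$t[ix])]
      for (k in seq_len(length(o) - 1)) {
        i1 <- vs[o[k]]; i2 <- vs[o[k + 1]]
        mid <- oracle_bisector_point(sites, a, b, pm, o[k], o[k + 1],
                                     vx, vy, i1, i2)
        dmid <- oracle_dvalid(sites, c(a, b), mid[1], mid[2])
        if (any(!is.finite(dmid))) next
        rm <- mean(dmid)
        empty <- TRUE
        for (j in seq_len(n)) {
          if (oracle_dclosed(sites, j, mid[1], mid[2]) < rm - tol * max(1, rm)) {
            empty <- FALSE; break
          }
        }
        if (!empty) next
        kind <- as.integer(xor(sites$type[a] == "point",
                               sites$type[b] == "point"))
        len <- sqrt((vx[i1] - vx[i2])^2 + (vy[i1] - vy[i2])^2)
        out$v1 <- c(out$v1, i1); out$v2 <- c(out$v2, i2)
        out$s1 <- c(out$s1, a); out$s2 <- c(out$s2, b)
        out$kind <- c(out$kind, kind); out$len <- c(out$len, len)
      }
    }
  }
  out
}

# parameter of points along the bisector of sites a, b (branch id separates
# the two angle-bisector lines of a segment/segment pair)
oracle_bisector_param <- function(sites, a, b, x, y) {
  ta <- sites$type[a]; tb <- sites$type[b]
  if (ta == "point" && tb == "point") {
    wx <- -(sites$y[b] - sites$y[a]); wy <- sites$x[b] - sites$x[a]
    l <- sqrt(wx^2 + wy^2); wx <- wx / l; wy <- wy / l
    list(t = x * wx + y * wy, branch = rep(1L, length(x)))
  } else if (ta == "segment" && tb == "segment") {
    u1 <- c(sites$x2[a] - sites$x1[a], sites$y2[a] - sites$y1[a])
    u1 <- u1 / sqrt(sum(u1^2))
    u2 <- c(sites$x2[b] - sites$x1[b], sites$y2[b] - sites$y1[b])
    u2 <- u2 / sqrt(sum(u2^2))
    w1 <- u1 + u2; w2 <- u1 - u2
    n1 <- sqrt(sum(w1^2)); n2 <- sqrt(sum(w2^2))
    if (n1 < 1e-12) { w1 <- c(-u1[2], u1[1]); n1 <- 1 }
    if (n2 < 1e-12) { w2 <- c(-u1[2], u1[1]); n2 <- 1 }
    w1 <- w1 / n1; w2 <- w2 / n2
    # assign each vertex to the nearer branch by signed-distance residual
    r1 <- residual_line(sites, a, b, x, y, w1)
    r2 <- residual_line(sites, a, b, x, y, w2)
    br <- ifelse(r1 <= r2, 1L, 2L)
    t <- ifelse(br == 1L, x * w1[1] + y * w1[2], x * w2[1] + y * w2[2])
    list(t = t, branch = br)
  } else {
    p <- if (ta == "point") a else b
    s <- if (ta == "point") b else a
    u <- c(sites$x2[s] - sites$x1[s], sites$y2[s] - sites$y1[s])
    u <- u / sqrt(sum(u^2))
    list(t = x * u[1] + y * u[2], branch = rep(1L, length(x)))
  }
}

# how far off each point is from the branch through direction w: distance
# from the point to the line {o + t w}, where o is any equidistant anchor
residual_line <- function(sites, a, b, x, y, w) {
  # use the pair of signed line distances: on one branch they are equal,
  # on the other they are opposite
  u1 <- c(sites$x2[a] - sites$x1[a], sites$y2[a] - sites$y1[a])
  u1 <- u1 / sqrt(sum(u1^2))
  u2 <- c(sites$x2[b] - sites$x1[b], sites$y2[b] - sites$y1[b])
  u2 <- u2 / sqrt(sum(u2^2))
  s1 <- (x - sites$x1[a]) * (-u1[2]) + (y - sites$y1[a]) * u1[1]
  s2 <- (x - sites$x1[b]) * (-u2[2]) + (y - sites$y1[b]) * u2[1]
  same <- abs(s1 - s2); opp <- abs(s1 + s2)
  # branch w1 = u1 + u2 corresponds to opposite-signed normals
  if (sum(w * (u1 + u2))^2 > sum(w * (u1 - u2))^2) opp else same
}

# midpoint between two vertices along the bisector (true parabola point for
# point/segment pairs)
oracle_bisector_point <- function(sites, a, b, pm, o1, o2, vx, vy, i1, i2) {
  ta <- sites$type[a]; tb <- sites$type[b]
  if (xor(ta == "point", tb == "point")) {
    p <- if (ta == "point") a else b
    s <- if (ta == "point") b else a
    u <- c(sites$x2[s] - sites$x1[s], sites$y2[s] - sites$y1[s])
    u <- u / sqrt(sum(u^2))
    tpar <- (sites$x[p] - sites$x1[s]) * u[1] + (sites$y[p] - sites$y1[s]) * u[2]
    f0 <- c(sites$x1[s], sites$y1[s]) + tpar * u
    pdist <- sqrt((sites$x[p] - f0[1])^2 + (sites$y[p] - f0[2])^2)
    if (pdist >= 1e-9) {
      ey <- (c(sites$x[p], sites$y[p]) - f0) / pdist
      ex <- c(-ey[2], ey[1])
      t1 <- (vx[i1] - f0[1]) * ex[1] + (vy[i1] - f0[2]) * ex[2]
      t2 <- (vx[i2] - f0[1]) * ex[1] + (vy[i2] - f0[2]) * ex[2]
      tm <- (t1 + t2) / 2
      eta <- (tm^2 + pdist^2) / (2 * pdist)
      return(f0 + tm * ex + eta * ey)
    }
  }
  c((vx[i1] + vx[i2]) / 2, (vy[i1] + vy[i2]) / 2)
}
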