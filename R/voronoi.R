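#' Build the shape graph (generalized Voronoi diagram) of traced boundaries
#'
#' Maps all boundaries of a segmented image onto one image-scale graph: the
#' generalized Voronoi diagram of every boundary vertex (point site) and
#' every boundary segment (open segment site), bounded by the image frame,
#' which enters as four segment sites plus four corner point sites and acts
#' as the outermost boundary. Each graph vertex is the centre of a maximal
#' circle tangent to three or more sites with no site inside (its
#' *clearance*); edges are bisector arcs (straight for point/point and
#' segment/segment pairs, parabolic for point/segment pairs). Vertices with
#' four or more co-tangent sites are split into coincident degree-3 vertices
#' joined by zero-length edges, so every vertex with positive clearance has
#' degree exactly 3.
#'
#' Consecutive collinear boundary segments are merged into single segment
#' sites before construction (the diagram is geometrically identical; the
#' merge removes the degenerate zero-width cells of straight-run vertices).
#'
#' @param boundaries a `shape_boundaries` tibble from
#'   [trace_binary_boundaries()] or [trace_label_boundaries()].
#' @param frame `c(xmin, ymin, xmax, ymax)` rectangle; defaults to the
#'   image frame recorded on `boundaries`. Use `NULL` for no frame (only
#'   supported for pure point input via [voronoi_diagram()]).
#' @param validate check that boundaries are simple and disjoint first.
#' @return A `shape_graph` object: a list of tibbles `vertices` (`vertex_id`,
#'   `x`, `y`, `clearance`), `edges` (`edge_id`, `v1`, `v2`, `site1`,
#'   `site2`, `curve_kind`, `length`), `tangents` (`vertex_id`, `site_id`,
#'   `tx`, `ty`), `sites`, plus the `boundaries` and `frame`.
#' @export
build_shape_graph <- function(boundaries, frame = attr(boundaries, "frame"),
                              validate = TRUE) {
  stopifnot(inherits(boundaries, "shape_boundaries"))
  if (validate) assert_boundaries_simple(boundaries)
  if (!is.null(frame)) {
    for (p in boundaries$points) {
      if (any(p[, 1] <= frame[1] + 1e-9) || any(p[, 1] >= frame[3] - 1e-9) ||
          any(p[, 2] <= frame[2] + 1e-9) || any(p[, 2] >= frame[4] - 1e-9)) {
        abort("boundaries touch or exceed the frame rectangle",
              class = "shapegraph_geometry_error")
      }
    }
  }
  sites <- boundary_sites(boundaries, frame)
  g <- voronoi_of_sites(sites, frame)
  g$boundaries <- boundaries
  g
}

#' Generalized Voronoi diagram of explicit point and segment sites
#'
#' Low-level interface used by [build_shape_graph()] and by the verification
#' tests. Segment endpoints must be listed among the points; `seg_p1` and
#' `seg_p2` give their row indices.
#'
#' @param points n x 2 matrix of point sites.
#' @param segments m x 4 matrix (`x1, y1, x2, y2`) of open segment sites
#'   (may have zero rows).
#' @param seg_p1,seg_p2 integer vectors: row in `points` of each segment's
#'   endpoints.
#' @param frame optional bounding rectangle `c(xmin, ymin, xmax, ymax)`
#'   added as four segment plus four point sites. Without a frame only pure
#'   point input is supported and unbounded edges get `v2 = NA`.
#' @param boundary_id optional integer per site (points then segments)
#'   recording which boundary each site belongs to; frame sites get 0.
#' @return A `shape_graph` object (without `boundaries`).
#' @export
voronoi_diagram <- function(points, segments = matrix(0, 0, 4),
                            seg_p1 = integer(), seg_p2 = integer(),
                            frame = NULL, boundary_id = NULL) {
  points <- as.matrix(points)
  segments <- as.matrix(segments)
  if (is.null(boundary_id)) {
    boundary_id <- rep(1L, nrow(points) + nrow(segments))
  }
  if (nrow(segments) > 0 && is.null(frame)) {
    abort("segment input requires a frame rectangle")
  }
  if (!is.null(frame)) {
    np0 <- nrow(points)
    ns0 <- nrow(segments)
    fx <- frame[c(1, 3)]; fy <- frame[c(2, 4)]
    fpts <- cbind(c(fx[1], fx[2], fx[2], fx[1]),
                  c(fy[1], fy[1], fy[2], fy[2]))
    fsegs <- cbind(fpts, fpts[c(2, 3, 4, 1), ])
    points <- rbind(points, fpts)
    segments <- rbind(segments, fsegs)
    seg_p1 <- c(seg_p1, np0 + 1:4)
    seg_p2 <- c(seg_p2, np0 + c(2, 3, 4, 1))
    boundary_id <- c(boundary_id[seq_len(np0)], rep(0L, 4),
                     boundary_id[np0 + seq_len(ns0)], rep(0L, 4))
  }
  sites <- tibble(
    site_id = seq_len(nrow(points) + nrow(segments)),
    type = rep(c("point", "segment"), c(nrow(points), nrow(segments))),
    boundary_id = as.integer(boundary_id),
    x = c(points[, 1], rep(NA_real_, nrow(segments))),
    y = c(points[, 2], rep(NA_real_, nrow(segments))),
    x1 = c(rep(NA_real_, nrow(points)), segments[, 1]),
    y1 = c(rep(NA_real_, nrow(points)), segments[, 2]),
    x2 = c(rep(NA_real_, nrow(points)), segments[, 3]),
    y2 = c(rep(NA_real_, nrow(points)), segments[, 4]),
    p1 = c(rep(NA_integer_, nrow(points)), as.integer(seg_p1)),
    p2 = c(rep(NA_integer_, nrow(points)), as.integer(seg_p2)),
    arc0 = NA_real_, arc1 = NA_real_,
    dix = NA_real_, diy = NA_real_, dox = NA_real_, doy = NA_real_
  )
  voronoi_of_sites(sites, frame)
}

# ---- site table construction -------------------------------------------

# Merge consecutive collinear ring segments and emit the site table for the
# engine. Point sites keep their incoming/outgoing ring directions (dix/diy,
# dox/doy) for material-side tests, and every site records the arc-length
# interval [arc0, arc1] it covers along its boundary.
boundary_sites <- function(boundaries, frame = NULL) {
  pts <- list(); segs <- list()
  for (i in seq_len(nrow(boundaries))) {
    p <- boundaries$points[[i]]
    bid <- boundaries$boundary_id[i]
    n <- nrow(p)
    arc <- ring_arcpos(p)
    per <- boundaries$perimeter[i]
    nxt <- c(2:n, 1L); prv <- c(n, 1:(n - 1L))
    d_out <- p[nxt, , drop = FALSE] - p
    d_in <- p - p[prv, , drop = FALSE]
    crossz <- d_in[, 1] * d_out[, 2] - d_in[, 2] * d_out[, 1]
    dotz <- d_in[, 1] * d_out[, 1] + d_in[, 2] * d_out[, 2]
    keep <- which(abs(crossz) > 1e-12 | dotz <= 0)
    if (length(keep) < 3) {
      abort(sprintf("boundary %d has fewer than 3 corners", bid),
            class = "shapegraph_geometry_error")
    }
    k <- length(keep)
    knxt <- c(keep[-1], keep[1])
    pts[[length(pts) + 1L]] <- tibble(
      boundary_id = bid, x = p[keep, 1], y = p[keep, 2], arc0 = arc[keep],
      dix = d_in[keep, 1] / sqrt(rowSums(d_in[keep, , drop = FALSE]^2)),
      diy = d_in[keep, 2] / sqrt(rowSums(d_in[keep, , drop = FALSE]^2)),
      dox = d_out[keep, 1] / sqrt(rowSums(d_out[keep, , drop = FALSE]^2)),
      doy = d_out[keep, 2] / sqrt(rowSums(d_out[keep, , drop = FALSE]^2))
    )
    segs[[length(segs) + 1L]] <- tibble(
      boundary_id = bid,
      x1 = p[keep, 1], y1 = p[keep, 2],
      x2 = p[knxt, 1], y2 = p[knxt, 2],
      arc0 = arc[keep],
      arc1 = ifelse(arc[knxt] > arc[keep], arc[knxt], per + arc[knxt]),
      pt_local_1 = seq_len(k),
      pt_local_2 = c(2:k, 1L)
    )
  }
  ptab <- if (length(pts)) list_rbind(pts) else
    tibble(boundary_id = integer(), x = numeric(), y = numeric(),
           arc0 = numeric(), dix = numeric(), diy = numeric(),
           dox = numeric(), doy = numeric())
  stab <- if (length(segs)) list_rbind(segs) else
    tibble(boundary_id = integer(), x1 = numeric(), y1 = numeric(),
           x2 = numeric(), y2 = numeric(), arc0 = numeric(),
           arc1 = numeric(), pt_local_1 = integer(), pt_local_2 = integer())
  # local point indices -> global rows
  if (nrow(stab)) {
    off <- c(0, cumsum(map_int(pts, nrow)))
    ring_of_seg <- rep(seq_along(segs), map_int(segs, nrow))
    stab$p1 <- stab$pt_local_1 + off[ring_of_seg]
    stab$p2 <- stab$pt_local_2 + off[ring_of_seg]
  } else {
    stab$p1 <- integer(); stab$p2 <- integer()
  }
  if (!is.null(frame)) {
    fx <- frame[c(1, 3)]; fy <- frame[c(2, 4)]
    fpts <- tibble(boundary_id = 0L,
                   x = c(fx[1], fx[2], fx[2], fx[1]),
                   y = c(fy[1], fy[1], fy[2], fy[2]),
                   arc0 = NA_real_, dix = NA_real_, diy = NA_real_,
                   dox = NA_real_, doy = NA_real_)
    np0 <- nrow(ptab)
    fsegs <- tibble(boundary_id = 0L,
                    x1 = fpts$x, y1 = fpts$y,
                    x2 = fpts$x[c(2, 3, 4, 1)], y2 = fpts$y[c(2, 3, 4, 1)],
                    arc0 = NA_real_, arc1 = NA_real_,
                    pt_local_1 = NA_integer_, pt_local_2 = NA_integer_,
                    p1 = np0 + 1:4, p2 = np0 + c(2, 3, 4, 1))
    ptab <- bind_rows(ptab, fpts)
    stab <- bind_rows(stab, fsegs)
  }
  np <- nrow(ptab)
  tibble(
    site_id = seq_len(np + nrow(stab)),
    type = rep(c("point", "segment"), c(np, nrow(stab))),
    boundary_id = c(ptab$boundary_id, stab$boundary_id),
    x = c(ptab$x, rep(NA_real_, nrow(stab))),
    y = c(ptab$y, rep(NA_real_, nrow(stab))),
    x1 = c(rep(NA_real_, np), stab$x1),
    y1 = c(rep(NA_real_, np), stab$y1),
    x2 = c(rep(NA_real_, np), stab$x2),
    y2 = c(rep(NA_real_, np), stab$y2),
    p1 = c(rep(NA_integer_, np), as.integer(stab$p1)),
    p2 = c(rep(NA_integer_, np), as.integer(stab$p2)),
    arc0 = c(ptab$arc0, stab$arc0),
    arc1 = c(rep(NA_real_, np), stab$arc1),
    dix = c(ptab$dix, rep(NA_real_, nrow(stab))),
    diy = c(ptab$diy, rep(NA_real_, nrow(stab))),
    dox = c(ptab$dox, rep(NA_real_, nrow(stab))),
    doy = c(ptab$doy, rep(NA_real_, nrow(stab)))
  )
}

# ---- engine call + degenerate vertex splitting -------------------------

voronoi_of_sites <- function(sites, frame,
                             tol_tangent = 1e-7, tol_vertex = 1e-6) {
  is_pt <- sites$type == "point"
  pts <- cbind(sites$x[is_pt], sites$y[is_pt])
  segs <- cbind(sites$x1[!is_pt], sites$y1[!is_pt],
                sites$x2[!is_pt], sites$y2[!is_pt])
  # engine site ids: points 0..np-1 then segments
  res <- .voronoi_engine_cpp(
    pts, segs,
    as.integer(sites$p1[!is_pt] - 1L), as.integer(sites$p2[!is_pt] - 1L),
    if (is.null(frame)) numeric(0) else as.numeric(frame),
    tol_tangent, tol_vertex
  )
  # engine ids coincide with site_id because points precede segments
  g <- split_degenerate_vertices(res, tol_vertex)
  structure(list(vertices = g$vertices, edges = g$edges,
                 tangents = g$tangents, sites = sites,
                 frame = frame, boundaries = NULL),
            class = "shape_graph")
}

# fan-split physical vertices with k >= 4 tangent sites into k - 2
# coincident degree-3 vertices joined by zero-length edges
split_degenerate_vertices <- function(res, tol_vertex) {
  nv <- length(res$vx)
  tang <- tibble(vertex = res$tang_vertex, site = res$tang_site,
                 tx = res$tang_x, ty = res$tang_y)
  ktab <- tabulate(tang$vertex, nbins = nv)
  edges <- tibble(v1 = res$e_v1, v2 = res$e_v2, site1 = res$e_s1,
                  site2 = res$e_s2, kind = res$e_kind, length = res$e_len)
  # new vertex ids: simple vertices map to one id; degenerate to k - 2
  n_sub <- pmax(1L, ktab - 2L)
  first_id <- cumsum(c(1L, head(n_sub, -1L)))
  vx <- rep(res$vx, n_sub); vy <- rep(res$vy, n_sub)
  vr <- rep(res$vr, n_sub)
  # tangency table: simple vertices are remapped in bulk; only degenerate
  # (k >= 4) vertices need per-vertex fan bookkeeping
  deg_v <- which(ktab > 3L)
  tang_by_v <- split(seq_len(nrow(tang)),
                     factor(tang$vertex, levels = seq_len(nv)))
  simple_rows <- which(!(tang$vertex %in% deg_v))
  nt_simple <- list(vertex_id = first_id[tang$vertex[simple_rows]],
                    site_id = tang$site[simple_rows],
                    tx = tang$tx[simple_rows], ty = tang$ty[simple_rows])
  nt_deg <- list(vertex_id = integer(), site_id = integer(),
                 tx = numeric(), ty = numeric())
  ze <- list(v1 = integer(), v2 = integer(), site1 = integer(),
             site2 = integer())
  for (pv in deg_v) {
    rows <- tang_by_v[[pv]]
    k <- length(rows)
    for (j in seq_len(k - 2L)) {
      tri <- rows[c(1L, j + 1L, j + 2L)]
      nt_deg$vertex_id <- c(nt_deg$vertex_id, rep(first_id[pv] + j - 1L, 3L))
      nt_deg$site_id <- c(nt_deg$site_id, tang$site[tri])
      nt_deg$tx <- c(nt_deg$tx, tang$tx[tri])
      nt_deg$ty <- c(nt_deg$ty, tang$ty[tri])
    }
    if (k > 3L) {
      for (j in seq_len(k - 3L)) {
        ze$v1 <- c(ze$v1, first_id[pv] + j - 1L)
        ze$v2 <- c(ze$v2, first_id[pv] + j)
        ze$site1 <- c(ze$site1, tang$site[rows[1L]])
        ze$site2 <- c(ze$site2, tang$site[rows[j + 2L]])
      }
    }
  }
  # remap edge endpoints
  edge_sub <- function(pv, s1, s2) {
    k <- ktab[pv]
    if (k <= 3L) return(first_id[pv])
    rows <- tang_by_v[[pv]]
    ts <- tang$site[rows]
    i1 <- match(s1, ts); i2 <- match(s2, ts)
    if (is.na(i1) || is.na(i2)) return(first_id[pv])
    m <- if ((i1 %% k) + 1L == i2) i1 else if ((i2 %% k) + 1L == i1) i2 else NA
    if (is.na(m)) return(first_id[pv])
    sub <- if (m == 1L) 1L else if (m == k) k - 2L else m - 1L
    first_id[pv] + sub - 1L
  }
  if (nrow(edges)) {
    v1n <- first_id[edges$v1]
    v2n <- ifelse(is.na(edges$v2), NA_integer_, first_id[edges$v2])
    fix1 <- which(edges$v1 %in% deg_v)
    for (i in fix1) v1n[i] <- edge_sub(edges$v1[i], edges$site1[i],
                                       edges$site2[i])
    fix2 <- which(!is.na(edges$v2) & edges$v2 %in% deg_v)
    for (i in fix2) v2n[i] <- edge_sub(edges$v2[i], edges$site1[i],
                                       edges$site2[i])
    edges$v1 <- as.integer(v1n)
    edges$v2 <- as.integer(v2n)
  }
  edges <- bind_rows(edges,
                     tibble(v1 = ze$v1, v2 = ze$v2, site1 = ze$site1,
                            site2 = ze$site2, kind = 0L,
                            length = rep(0, length(ze$v1))))
  # two tritangent circles closer than the vertex-merge tolerance collapse
  # into one vertex; the leftover micro self-loop carries no structure
  edges <- edges[!(edges$v1 == edges$v2 & !is.na(edges$v2) &
                     edges$length < 1e-6), ]
  vertices <- tibble(vertex_id = seq_along(vx), x = vx, y = vy,
                     clearance = vr)
  fix <- repair_merged_grazings(vertices, edges,
                                c(nt_simple$vertex_id, nt_deg$vertex_id),
                                c(nt_simple$site_id, nt_deg$site_id),
                                c(nt_simple$tx, nt_deg$tx),
                                c(nt_simple$ty, nt_deg$ty))
  vertices <- fix$vertices
  edges <- fix$edges
  nt_all <- fix$tang
  tangents <- tibble(
    vertex_id = as.integer(nt_all$vertex_id),
    site_id = nt_all$site_id,
    tx = nt_all$tx, ty = nt_all$ty)
  tangents <- tangents[order(tangents$vertex_id), ]
  edges$edge_id <- seq_len(nrow(edges))
  edges$curve_kind <- ifelse(edges$kind == 1L, "parabolic", "line")
  edges$kind <- NULL
  list(vertices = vertices,
       edges = select(edges, "edge_id", "v1", "v2", "site1", "site2",
                      "curve_kind", "length"),
       tangents = tangents)
}

# Near-degenerate site configurations (e.g. the 1/20-px shift necks) can
# leave a cluster of vertices within ~1e-4 px whose edge bookkeeping is
# inconsistent (tritangent circle pairs captured twice, micro-cells
# collapsed). Rebuild each broken cluster as a clean chain of coincident
# degree-3 vertices joined by zero-length edges -- the cocircular-fan
# convention -- carrying all of the cluster's external edges. Clusters whose
# vertices already have degree 3 are left untouched, so well-conditioned
# diagrams are unchanged.
repair_merged_grazings <- function(vertices, edges, t_vertex, t_site,
                                   t_tx, t_ty) {
  tang <- list(vertex_id = t_vertex, site_id = t_site, tx = t_tx, ty = t_ty)
  deg <- tabulate(c(edges$v1, edges$v2[!is.na(edges$v2)]),
                  nbins = nrow(vertices))
  # under-connected clearance-0 vertices are legitimate (frame corners);
  # over-connected ones carry duplicated grazing edges and are rebuilt too
  broken <- which((deg != 3 & vertices$clearance > 1e-9) | deg > 3)
  if (!length(broken)) {
    return(list(vertices = vertices, edges = edges, tang = tang))
  }
  edges$rowkey__ <- seq_len(nrow(edges))
  drop_v <- integer(0)
  done <- rep(FALSE, nrow(vertices))
  for (b0 in broken) {
    if (b0 <= length(done) && done[b0]) next
    # coincidence cluster by position (within 1e-4)
    cl <- b0
    repeat {
      dx <- vertices$x - vertices$x[b0]
      dy <- vertices$y - vertices$y[b0]
      near <- which(sqrt(dx^2 + dy^2) < 1e-4)
      if (!length(setdiff(near, cl))) break
      cl <- union(cl, near)
      break  # one expansion is enough at this scale
    }
    done[cl] <- TRUE
    eid <- which(edges$v1 %in% cl | (!is.na(edges$v2) & edges$v2 %in% cl))
    internal <- eid[edges$v1[eid] %in% cl &
                      !is.na(edges$v2[eid]) & edges$v2[eid] %in% cl]
    external <- setdiff(eid, internal)
    # external ends as (rowkey, end slot)
    ends <- list()
    for (k in external) {
      if (edges$v1[k] %in% cl) {
        ends[[length(ends) + 1L]] <- c(edges$rowkey__[k], 1L)
      }
      if (!is.na(edges$v2[k]) && edges$v2[k] %in% cl) {
        ends[[length(ends) + 1L]] <- c(edges$rowkey__[k], 2L)
      }
    }
    n_ext <- length(ends)
    if (!n_ext) next
    rep_n <- max(1L, n_ext - 2L)
    best <- cl[which.max(vertices$clearance[cl])]
    reps <- cl[seq_len(min(rep_n, length(cl)))]
    while (length(reps) < rep_n) {
      w <- nrow(vertices) + 1L
      vertices <- bind_rows(vertices,
                            tibble(vertex_id = w, x = vertices$x[best],
                                   y = vertices$y[best],
                                   clearance = vertices$clearance[best]))
      reps <- c(reps, w)
      done <- c(done, TRUE)
    }
    drop_v <- c(drop_v, setdiff(cl, reps))
    vertices$x[reps] <- vertices$x[best]
    vertices$y[reps] <- vertices$y[best]
    vertices$clearance[reps] <- vertices$clearance[best]
    if (length(internal)) edges <- edges[-internal, ]
    # assign external ends around the chain: first and last rep take two
    idx <- if (rep_n == 1) rep(1L, n_ext) else {
      c(1L, 1L, if (rep_n > 2) 2:(rep_n - 1L), rep_n, rep_n)
    }
    for (q in seq_along(ends)) {
      row <- which(edges$rowkey__ == ends[[q]][1])
      if (!length(row)) next
      if (ends[[q]][2] == 1L) edges$v1[row] <- reps[idx[q]]
      else edges$v2[row] <- reps[idx[q]]
    }
    if (rep_n > 1) {
      ts <- sort(unique(tang$site_id[tang$vertex_id %in% cl]))
      pr <- if (length(ts) >= 2) ts[1:2] else c(1L, 1L)
      edges <- bind_rows(edges,
                         tibble(v1 = reps[-rep_n], v2 = reps[-1],
                                site1 = pr[1], site2 = pr[2], kind = 0L,
                                length = 0,
                                rowkey__ = NA_integer_))
    }
    # tangent records: the union over the cluster, copied to every rep
    sel <- which(tang$vertex_id %in% cl)
    usel <- sel[!duplicated(tang$site_id[sel])]
    keep <- !(tang$vertex_id %in% cl)
    add_v <- rep(reps, each = length(usel))
    tang <- list(
      vertex_id = c(tang$vertex_id[keep], add_v),
      site_id = c(tang$site_id[keep], rep(tang$site_id[usel], length(reps))),
      tx = c(tang$tx[keep], rep(tang$tx[usel], length(reps))),
      ty = c(tang$ty[keep], rep(tang$ty[usel], length(reps))))
  }
  edges$rowkey__ <- NULL
  if (length(drop_v)) {
    keep_v <- setdiff(seq_len(nrow(vertices)), drop_v)
    newid <- rep(NA_integer_, nrow(vertices))
    newid[keep_v] <- seq_along(keep_v)
    vertices <- vertices[keep_v, ]
    vertices$vertex_id <- seq_len(nrow(vertices))
    edges$v1 <- newid[edges$v1]
    edges$v2 <- ifelse(is.na(edges$v2), NA_integer_, newid[edges$v2])
    tkeep <- tang$vertex_id %in% keep_v
    tang <- list(vertex_id = newid[tang$vertex_id[tkeep]],
                 site_id = tang$site_id[tkeep],
                 tx = tang$tx[tkeep], ty = tang$ty[tkeep])
  }
  list(vertices = vertices, edges = edges, tang = tang)
}

#' @export
print.shape_graph <- function(x, ...) {
  cat(sprintf(
    "<shape_graph> %d vertices, %d edges, %d sites%s\n",
    nrow(x$vertices), nrow(x$edges), nrow(x$sites),
    if (!is.null(x$boundaries)) sprintf(", %d boundaries",
                                        nrow(x$boundaries)) else ""))
  if (!is.null(x$vertices$side)) {
    cat("  sides:", paste(sprintf("%s=%d", names(table(x$vertices$side)),
                                  table(x$vertices$side)), collapse = " "),
        "\n")
  }
  invisible(x)
}

# point on the bisector curve of an edge at relative position s in [0, 1]
# (exact for straight edges; true parabola point for parabolic edges)
edge_point <- function(graph, edge_row, s = 0.5) {
  e <- edge_row
  v1 <- graph$vertices[e$v1, ]; v2 <- graph$vertices[e$v2, ]
  if (e$curve_kind != "parabolic") {
    return(c((1 - s) * v1$x + s * v2$x, (1 - s) * v1$y + s * v2$y))
  }
  s1 <- graph$sites[e$site1, ]; s2 <- graph$sites[e$site2, ]
  pt <- if (s1$type == "point") s1 else s2
  sg <- if (s1$type == "point") s2 else s1
  u <- c(sg$x2 - sg$x1, sg$y2 - sg$y1)
  u <- u / sqrt(sum(u^2))
  f0t <- (pt$x - sg$x1) * u[1] + (pt$y - sg$y1) * u[2]
  f0 <- c(sg$x1, sg$y1) + f0t * u
  p <- sqrt((pt$x - f0[1])^2 + (pt$y - f0[2])^2)
  if (p < 1e-9) {  # spoke: straight
    return(c((1 - s) * v1$x + s * v2$x, (1 - s) * v1$y + s * v2$y))
  }
  ey <- (c(pt$x, pt$y) - f0) / p
  ex <- c(-ey[2], ey[1])
  t1 <- (v1$x - f0[1]) * ex[1] + (v1$y - f0[2]) * ex[2]
  t2 <- (v2$x - f0[1]) * ex[1] + (v2$y - f0[2]) * ex[2]
  tm <- (1 - s) * t1 + s * t2
  eta <- (tm^2 + p^2) / (2 * p)
  f0 + tm * ex + eta * ey
}
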