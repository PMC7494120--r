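#' Annotate a shape graph with sides, roles, and subgraph structure
#'
#' Splits the graph into the *in-graph* (foreground material) and *out-graph*
#' (background), classifies vertices as bridges (equidistant to exactly two
#' distinct boundaries), hubs (three or more), connectors, or plain branch
#' vertices, and records the distinct equidistant boundaries per vertex.
#'
#' Sides are determined geometrically, not by pixel lookup: every vertex and
#' edge midpoint is tested against the material side of a tangent boundary
#' site (boundaries are traced with the foreground on the left). Edges
#' generated by a frame site are tagged `"frame"`. Vertices with clearance
#' ~0 lie exactly on a boundary (they are the leaves where the graph meets
#' the boundary) and get side `"boundary"`; the image frame itself counts
#' as boundary 0, so vertices between content and frame are bridges.
#'
#' @param graph a `shape_graph` from [build_shape_graph()].
#' @return The graph with `side` and `role` columns added to `vertices`,
#'   `side` and `owner_boundary` added to `edges`, and an
#'   `equidistant` list-column of boundary ids on `vertices`.
#' @export
annotate_graph <- function(graph) {
  stopifnot(inherits(graph, "shape_graph"))
  sites <- graph$sites
  verts <- graph$vertices
  edges <- graph$edges
  tang <- graph$tangents

  tang$boundary_id <- sites$boundary_id[tang$site_id]
  eq <- tang %>%
    group_by(.data$vertex_id) %>%
    summarise(bnds = list(sort(unique(.data$boundary_id))), .groups = "drop")
  verts$equidistant <- vector("list", nrow(verts))
  verts$equidistant[eq$vertex_id] <- eq$bnds

  # ---- vertex sides (vectorized) ----
  nv <- nrow(verts)
  # first content tangency per vertex
  ct <- tang[tang$boundary_id > 0L, ]
  first <- !duplicated(ct$vertex_id)
  ct <- ct[first, ]
  sid <- rep(NA_integer_, nv); ftx <- fty <- rep(NA_real_, nv)
  sid[ct$vertex_id] <- ct$site_id
  ftx[ct$vertex_id] <- ct$tx; fty[ct$vertex_id] <- ct$ty
  side <- rep(NA_character_, nv)
  low <- verts$clearance <= 1e-7
  side[low & !is.na(sid)] <- "boundary"
  side[low & is.na(sid)] <- "frame"
  side[!low & is.na(sid)] <- "frame"
  idx <- which(!low & !is.na(sid))
  if (length(idx)) {
    side[idx] <- material_side_vec(sites, verts$x[idx], verts$y[idx],
                                   sid[idx], ftx[idx], fty[idx])
  }
  verts$side <- side

  # ---- edge sides (vectorized) ----
  b1 <- sites$boundary_id[edges$site1]
  b2 <- sites$boundary_id[edges$site2]
  edges$side <- rep(NA_character_, nrow(edges))
  edges$side[b1 == 0L | b2 == 0L] <- "frame"
  vside <- verts$side
  s1v <- vside[edges$v1]
  s2v <- ifelse(is.na(edges$v2), NA_character_, vside[edges$v2])
  open_ <- is.na(edges$side)
  pick <- open_ & s1v %in% c("in", "out")
  edges$side[pick] <- s1v[pick]
  pick2 <- is.na(edges$side) & !is.na(s2v) & s2v %in% c("in", "out")
  edges$side[pick2] <- s2v[pick2]
  todo <- which(is.na(edges$side))
  if (length(todo)) {
    # both endpoints on boundaries: probe the curve midpoint (true chord for
    # straight edges; exact parabola point otherwise)
    mx <- (verts$x[edges$v1[todo]] + verts$x[edges$v2[todo]]) / 2
    my <- (verts$y[edges$v1[todo]] + verts$y[edges$v2[todo]]) / 2
    par <- which(edges$curve_kind[todo] == "parabolic")
    for (k in par) {
      m <- edge_point(graph, edges[todo[k], ], 0.5)
      mx[k] <- m[1]; my[k] <- m[2]
    }
    sid <- ifelse(b1[todo] > 0L, edges$site1[todo], edges$site2[todo])
    ft <- site_feet_vec(sites, sid, mx, my)
    edges$side[todo] <- material_side_vec(sites, mx, my, sid,
                                          ft[, 1], ft[, 2])
  }
  edges$owner_boundary <- ifelse(b1 == 0L, b2, ifelse(b2 == 0L, b1,
                                                      pmin(b1, b2)))

  # ---- roles ----
  nb <- map_int(verts$equidistant, function(b) {
    if (is.null(b)) 0L else length(b)
  })
  verts$role <- case_when(nb >= 3L ~ "hub", nb == 2L ~ "bridge",
                          TRUE ~ "branch")
  graph$vertices <- verts
  graph$edges <- edges
  graph$tangents <- tang
  graph
}

# vectorized material-side test: for each point (px, py) with tangent site
# sid and tangency foot (fx, fy), decide "in" (foreground) or "out"
material_side_vec <- function(sites, px, py, sid, fx, fy) {
  out <- rep(NA_character_, length(px))
  st <- sites$type[sid]
  seg <- which(st == "segment")
  if (length(seg)) {
    s <- sid[seg]
    dx <- sites$x2[s] - sites$x1[s]; dy <- sites$y2[s] - sites$y1[s]
    lefts <- dx * (py[seg] - fy[seg]) - dy * (px[seg] - fx[seg])
    out[seg] <- ifelse(lefts > 0, "in", "out")
  }
  pt <- which(st == "point")
  if (length(pt)) {
    s <- sid[pt]
    ux <- px[pt] - sites$x[s]; uy <- py[pt] - sites$y[s]
    ci <- sites$dix[s] * uy - sites$diy[s] * ux
    co <- sites$dox[s] * uy - sites$doy[s] * ux
    turn <- sites$dix[s] * sites$doy[s] - sites$diy[s] * sites$dox[s]
    inside <- ifelse(turn > 0, ci > 0 & co > 0, ci > 0 | co > 0)
    out[pt] <- ifelse(inside, "in", "out")
  }
  out
}

# which material side of boundary site `sid` is the point (px, py) on;
# (fx, fy) is the site's tangency foot for that point. Boundaries are traced
# with the foreground on the left of the travel direction.
material_side_point <- function(graph, px, py, sid, fx, fy) {
  s <- graph$sites[sid, ]
  if (s$boundary_id == 0L) return("frame")
  if (s$type == "segment") {
    d <- c(s$x2 - s$x1, s$y2 - s$y1)
    lefts <- d[1] * (py - fy) - d[2] * (px - fx)  # cross(d, p - foot)
    if (lefts > 0) "in" else "out"
  } else {
    u <- c(px - s$x, py - s$y)
    ci <- s$dix * u[2] - s$diy * u[1]   # cross(d_in, u)
    co <- s$dox * u[2] - s$doy * u[1]   # cross(d_out, u)
    turn <- s$dix * s$doy - s$diy * s$dox
    inside <- if (turn > 0) (ci > 0 && co > 0) else (ci > 0 || co > 0)
    if (inside) "in" else "out"
  }
}

# vectorized closed feet of points on sites
site_feet_vec <- function(sites, sid, px, py) {
  fx <- rep(NA_real_, length(sid)); fy <- rep(NA_real_, length(sid))
  pt <- which(sites$type[sid] == "point")
  if (length(pt)) {
    fx[pt] <- sites$x[sid[pt]]; fy[pt] <- sites$y[sid[pt]]
  }
  sg <- which(sites$type[sid] == "segment")
  if (length(sg)) {
    s <- sid[sg]
    ux <- sites$x2[s] - sites$x1[s]; uy <- sites$y2[s] - sites$y1[s]
    len <- sqrt(ux^2 + uy^2); ux <- ux / len; uy <- uy / len
    t <- pmin(pmax((px[sg] - sites$x1[s]) * ux +
                     (py[sg] - sites$y1[s]) * uy, 0), len)
    fx[sg] <- sites$x1[s] + t * ux
    fy[sg] <- sites$y1[s] + t * uy
  }
  cbind(fx, fy)
}

site_foot <- function(s, px, py) {
  if (s$type == "point") return(c(s$x, s$y))
  u <- c(s$x2 - s$x1, s$y2 - s$y1)
  len <- sqrt(sum(u^2)); u <- u / len
  t <- (px - s$x1) * u[1] + (py - s$y1) * u[2]
  t <- min(max(t, 0), len)
  c(s$x1 + t * u[1], s$y1 + t * u[2])
}

#' Partition an annotated graph into per-boundary subgraphs
#'
#' Every non-frame edge is assigned to one `(boundary, side)` subgraph: the
#' boundary generating it; an edge whose two generating sites belong to
#' different boundaries is a root-path (bridge) edge shared between the two
#' subgraphs, and its unique owner for the partition is the lower boundary
#' id. [subgraph_of()] returns the inclusive edge set used for profile
#' computations (bridge edges appear in both adjacent subgraphs).
#'
#' @param graph an annotated `shape_graph`.
#' @return A tibble with one row per (boundary, side) subgraph:
#'   `boundary_id`, `side`, `n_vertices`, `n_edges`, and list columns
#'   `vertex_ids`, `edge_ids` (inclusive sets).
#' @export
partition_subgraphs <- function(graph) {
  stopifnot(!is.null(graph$edges$side))
  edges <- graph$edges
  sites <- graph$sites
  content <- edges$side %in% c("in", "out")
  b1 <- sites$boundary_id[edges$site1]
  b2 <- sites$boundary_id[edges$site2]
  rows <- list()
  for (side in c("in", "out")) {
    sel <- which(content & edges$side == side)
    if (!length(sel)) next
    bnds <- sort(unique(c(b1[sel], b2[sel])))
    bnds <- bnds[bnds > 0L]
    for (b in bnds) {
      eids <- sel[b1[sel] == b | b2[sel] == b]
      vids <- sort(unique(c(edges$v1[eids], edges$v2[eids])))
      vids <- vids[!is.na(vids)]
      rows[[length(rows) + 1L]] <- tibble(
        boundary_id = b, side = side,
        n_vertices = length(vids), n_edges = length(eids),
        vertex_ids = list(vids), edge_ids = list(eids))
    }
  }
  if (!length(rows)) {
    return(tibble(boundary_id = integer(), side = character(),
                  n_vertices = integer(), n_edges = integer(),
                  vertex_ids = list(), edge_ids = list()))
  }
  list_rbind(rows)
}

#' Extract one (boundary, side) subgraph
#'
#' @param graph an annotated `shape_graph`.
#' @param boundary_id boundary id.
#' @param side `"in"` or `"out"`.
#' @return A `shape_subgraph` list: `boundary_id`, `side`, `vertex_ids`,
#'   `edges` (rows of the graph's edge table), and the parent `graph`.
#' @export
subgraph_of <- function(graph, boundary_id, side = c("in", "out")) {
  side <- match.arg(side)
  sites <- graph$sites
  edges <- graph$edges
  b1 <- sites$boundary_id[edges$site1]
  b2 <- sites$boundary_id[edges$site2]
  eids <- which(edges$side == side & (b1 == boundary_id | b2 == boundary_id))
  vids <- sort(unique(c(edges$v1[eids], edges$v2[eids])))
  vids <- vids[!is.na(vids)]
  structure(list(boundary_id = boundary_id, side = side,
                 vertex_ids = vids, edge_ids = eids,
                 graph = graph),
            class = "shape_subgraph")
}

#' @export
print.shape_subgraph <- function(x, ...) {
  cat(sprintf("<shape_subgraph> boundary %d, %s-side: %d vertices, %d edges\n",
              x$boundary_id, x$side, length(x$vertex_ids),
              length(x$edge_ids)))
  invisible(x)
}

#' Root path of a subgraph
#'
#' If the subgraph contains bridge/hub vertices (equidistant to the owning
#' boundary and at least one other boundary, the frame included), the root
#' path is the continuous chain of those vertices plus any connector
#' vertices needed to join disconnected bridge runs (cyclic when the chain
#' closes). Otherwise the subgraph is a tree: the root is its
#' maximal-clearance vertex and the root path is the longest leaf-to-leaf
#' path through the root.
#'
#' @param subgraph a `shape_subgraph` from [subgraph_of()].
#' @return A list: `vertex_ids` (ordered along the path), `cyclic`,
#'   `arc` (cumulative path length at each vertex), `root_id`
#'   (maximal-clearance vertex on the path).
#' @export
root_path <- function(subgraph) {
  g <- subgraph$graph
  if (!length(subgraph$edge_ids)) {
    abort("empty subgraph", class = "shapegraph_empty_error")
  }
  edges <- g$edges[subgraph$edge_ids, ]
  b <- subgraph$boundary_id
  sb1 <- g$sites$boundary_id[edges$site1]
  sb2 <- g$sites$boundary_id[edges$site2]
  # root vertices: on edges whose two sites belong to different boundaries
  redge <- which(sb1 != sb2)
  root_v <- sort(unique(c(edges$v1[redge], edges$v2[redge])))
  # also vertices whose tangent set spans 2+ boundaries (incl. frame),
  # restricted to this subgraph
  vb <- g$vertices$equidistant[subgraph$vertex_ids]
  multi <- subgraph$vertex_ids[map_int(vb, length) >= 2L]
  root_v <- sort(union(root_v, multi))
  if (length(root_v)) {
    # the chain of an outermost boundary runs through content-frame bridge
    # edges (side "frame"); include those whose both ends are root vertices
    fr <- g$edges[g$edges$side == "frame" & !is.na(g$edges$v2) &
                    g$edges$v1 %in% root_v & g$edges$v2 %in% root_v, ]
    seq_ids <- order_root_chain(g, bind_rows(edges, fr), root_v)
    path <- seq_ids$ids
    cyc <- seq_ids$cyclic
    has_bridges <- TRUE
  } else {
    dia <- tree_diameter_through_root(g, edges, subgraph$vertex_ids)
    path <- dia$ids
    cyc <- FALSE
    has_bridges <- FALSE
  }
  cl <- g$vertices$clearance[path]
  xy <- cbind(g$vertices$x[path], g$vertices$y[path])
  # arc positions along the path (straight-line between consecutive path
  # vertices; bisector chords at this scale)
  if (length(path) > 1) {
    dd <- sqrt(rowSums((xy[-1, , drop = FALSE] -
                          xy[-nrow(xy), , drop = FALSE])^2))
    arc <- c(0, cumsum(dd))
  } else arc <- 0
  # canonical origin: maximal clearance vertex first for cyclic paths
  if (cyc && length(path) > 2) {
    k <- which.max(cl)
    idx <- c(k:length(path), seq_len(k - 1L))
    path <- path[idx]; cl <- cl[idx]
    xy <- xy[idx, , drop = FALSE]
    dd <- sqrt(rowSums((xy[-1, , drop = FALSE] -
                          xy[-nrow(xy), , drop = FALSE])^2))
    arc <- c(0, cumsum(dd))
  }
  list(vertex_ids = path, cyclic = cyc, arc = arc,
       root_id = path[which.max(cl)], has_bridges = has_bridges)
}

# order the root vertices into a chain/cycle, joining disconnected runs by
# shortest paths through the subgraph (those joining vertices = connectors)
order_root_chain <- function(g, edges, root_v) {
  ig <- subgraph_igraph(edges)
  rv <- as.character(root_v)
  present <- rv %in% igraph::V(ig)$name
  rv <- rv[present]
  if (!length(rv)) return(list(ids = root_v[1], cyclic = FALSE))
  sub <- igraph::induced_subgraph(ig, rv)
  comp <- igraph::components(sub)
  # join components through the full subgraph
  member_sets <- split(names(comp$membership), comp$membership)
  chain_v <- rv
  guard <- length(member_sets) + 2L
  while (length(member_sets) > 1 && guard > 0) {
    guard <- guard - 1L
    a <- member_sets[[1]]
    rest <- unlist(member_sets[-1])
    d <- suppressWarnings(
      igraph::distances(ig, v = a, to = rest, weights = igraph::E(ig)$w))
    if (!any(is.finite(d))) break  # genuinely disconnected: keep first run
    ij <- which(d == min(d[is.finite(d)]), arr.ind = TRUE)[1, ]
    sp <- igraph::shortest_paths(ig, from = a[ij[1]], to = rest[ij[2]],
                                 weights = igraph::E(ig)$w)$vpath[[1]]
    chain_v <- union(chain_v, names(sp))
    sub <- igraph::induced_subgraph(ig, chain_v)
    comp <- igraph::components(sub)
    member_sets <- split(names(comp$membership), comp$membership)
  }
  if (length(member_sets) > 1) {
    # fall back to the largest connected run
    big <- which.max(lengths(member_sets))
    sub <- igraph::induced_subgraph(ig, member_sets[[big]])
  }
  # walk the chain: vertices of degree <= 2 expected; tolerate short spurs
  deg <- igraph::degree(sub)
  cyclic <- all(deg == 2) && length(deg) > 2
  if (cyclic) {
    start <- igraph::V(sub)$name[1]
    ord <- walk_cycle(sub, start)
  } else {
    ends <- names(deg)[deg <= 1]
    if (!length(ends)) ends <- names(deg)[1]
    # longest path between degree-1 ends through the chain
    dd <- igraph::distances(sub, v = ends, to = ends,
                            weights = igraph::E(sub)$w)
    dd[!is.finite(dd)] <- -1
    ij <- which(dd == max(dd), arr.ind = TRUE)[1, ]
    sp <- igraph::shortest_paths(sub, from = ends[ij[1]], to = ends[ij[2]],
                                 weights = igraph::E(sub)$w)$vpath[[1]]
    ord <- names(sp)
  }
  list(ids = as.integer(ord), cyclic = cyclic)
}

walk_cycle <- function(sub, start) {
  ord <- character(igraph::vcount(sub))
  prev <- ""
  cur <- start
  for (i in seq_along(ord)) {
    ord[i] <- cur
    nb <- igraph::V(sub)$name[igraph::neighbors(sub, cur)]
    nxt <- setdiff(nb, c(prev, cur))
    if (!length(nxt)) break
    prev <- cur
    cur <- nxt[1]
  }
  ord[nzchar(ord)]
}

# igraph over an edge table (vertex names = vertex ids)
subgraph_igraph <- function(edges) {
  e <- edges[!is.na(edges$v2), ]
  el <- cbind(as.character(e$v1), as.character(e$v2))
  ig <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::E(ig)$w <- pmax(e$length, 0)
  ig
}

# longest leaf-to-leaf path through the maximal-clearance vertex of a tree
tree_diameter_through_root <- function(g, edges, vertex_ids) {
  cl <- g$vertices$clearance[vertex_ids]
  root <- vertex_ids[which.max(cl)]
  lg <- local_edge_graph(edges)
  src <- match(root, lg$vids)
  if (is.na(src)) return(list(ids = root))
  res <- .dijkstra_cpp(length(lg$vids), lg$ei, lg$ej, lg$w,
                       as.integer(src), 0)
  d <- res$dist[-1]; parent <- res$parent[-1]; branch <- res$branch[-1]
  reach <- which(is.finite(d) & branch > 0)
  reach <- reach[reach != src]
  if (!length(reach)) return(list(ids = root))
  # farthest vertex within each first-hop branch of the root
  far <- tapply(reach, branch[reach], function(ix) ix[which.max(d[ix])])
  far <- unlist(far)
  ord <- order(d[far], decreasing = TRUE)
  walk_up <- function(v) {
    path <- v
    while (v != src && parent[v] > 0) {
      v <- parent[v]
      path <- c(path, v)
    }
    path
  }
  ids1 <- lg$vids[walk_up(far[ord[1]])]           # leaf ... root
  if (length(far) >= 2) {
    ids2 <- lg$vids[rev(walk_up(far[ord[2]]))]    # root ... leaf
    ids <- c(ids1, ids2[-1])
  } else ids <- ids1
  list(ids = ids)
}

#' Mark connector vertices on an annotated graph
#'
#' Connectors are branch vertices that lie on a root path between bridge
#' runs of the same boundary (the hole-within-a-protrusion case). They are
#' identified per subgraph by [root_path()]; this helper updates the
#' vertex roles accordingly.
#'
#' @param graph an annotated `shape_graph`.
#' @return The graph with `role` upgraded to `"connector"` where applicable.
#' @export
classify_connectors <- function(graph) {
  parts <- partition_subgraphs(graph)
  for (i in seq_len(nrow(parts))) {
    sg <- subgraph_of(graph, parts$boundary_id[i], parts$side[i])
    rp <- tryCatch(root_path(sg), error = function(e) NULL)
    if (is.null(rp)) next
    on_path <- rp$vertex_ids
    br <- graph$vertices$role[on_path]
    upgrade <- on_path[br == "branch"]
    if (length(upgrade) && any(br %in% c("bridge", "hub"))) {
      graph$vertices$role[upgrade] <- "connector"
    }
  }
  graph
}
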