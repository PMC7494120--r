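#' Width profile of a subgraph
#'
#' The clearance radii of the inscribed circles centred at the root-path
#' vertices, against cumulative arc position along the root path. In the
#' foreground this is the local width of the structure; in the background,
#' the local sparsity.
#'
#' @param subgraph a `shape_subgraph` from [subgraph_of()].
#' @param rp a precomputed [root_path()] (computed if `NULL`).
#' @return A tibble with columns `arc` (px) and `radius` (px), plus
#'   attributes `cyclic` and `root_id`.
#' @export
width_profile <- function(subgraph, rp = NULL) {
  if (is.null(rp)) rp <- root_path(subgraph)
  g <- subgraph$graph
  ids <- rp$vertex_ids
  arc <- rp$arc
  r <- g$vertices$clearance[ids]
  # coincident fan vertices are one geometric sample; boundary leaves at the
  # ends of a tree diameter have no inscribed circle to report
  keep <- !(c(FALSE, diff(arc) < 1e-9)) & r > 1e-9
  out <- tibble(arc = arc[keep], radius = r[keep])
  attr(out, "cyclic") <- rp$cyclic
  attr(out, "root_id") <- rp$root_id
  attr(out, "vertex_ids") <- ids[keep]
  out
}

#' Boundary profile of a subgraph
#'
#' For every point along the boundary, the shortest distance along the
#' subgraph edges from the root path to the leaf vertex tangent to that
#' point, minus the clearance of the root vertex where that shortest path
#' begins. This measures protrusions and bumps independently of the overall
#' width (a point tangent to a root vertex's circle has height ~0).
#'
#' Heights are sampled at every vertex of the traced boundary polyline, in
#' boundary order; each sample takes the height of the tangency whose
#' position along the boundary is nearest (tangencies exist at every
#' boundary corner -- the clearance-0 leaf vertices -- and along segments).
#'
#' @param subgraph a `shape_subgraph`.
#' @param rp a precomputed [root_path()] (computed if `NULL`).
#' @return A tibble with columns `arc` (boundary arc length, px) and
#'   `height` (px).
#' @export
boundary_profile <- function(subgraph, rp = NULL) {
  g <- subgraph$graph
  b <- subgraph$boundary_id
  if (is.null(rp)) rp <- root_path(subgraph)
  hts <- subgraph_heights(subgraph, rp)
  # tangencies on the owning boundary with their boundary arc positions
  tg <- g$tangents
  tg <- tg[tg$vertex_id %in% subgraph$vertex_ids &
             g$sites$boundary_id[tg$site_id] == b, ]
  if (!nrow(tg)) abort("boundary has no tangent leaves (corrupt subgraph)")
  per0 <- g$boundaries$perimeter[[match(b, g$boundaries$boundary_id)]]
  # sites covering the ring's wrap point carry arcs beyond the perimeter
  tg$arc <- tangency_arc(g$sites, tg$site_id, tg$tx, tg$ty) %% per0
  # height at a tangency of vertex v: distance from the root set along the
  # subgraph to v, plus the radial drop from v's circle to the boundary
  # (its clearance), minus the clearance of the root where the path starts
  # (already folded into the multi-source distances)
  tg$clearance <- g$vertices$clearance[tg$vertex_id]
  tg$height <- hts[as.character(tg$vertex_id)] + tg$clearance
  tg <- tg[is.finite(tg$height), ]
  tg <- tg[order(tg$arc, tg$height, tg$vertex_id), ]
  same <- c(FALSE, diff(tg$arc) < 1e-7)
  tg <- tg[!same, ]
  ring <- g$boundaries$points[[match(b, g$boundaries$boundary_id)]]
  per <- g$boundaries$perimeter[[match(b, g$boundaries$boundary_id)]]
  samples <- ring_arcpos(ring)
  # nearest tangency (circularly) per sample arc
  idx <- nearest_circular(tg$arc, samples, per)
  tibble(arc = samples, height = tg$height[idx])
}

# Multi-source shortest path distances from the root vertices, each source
# starting at -clearance (so distances are already normalized). With
# bridges, the sources are the whole root path; for a bridge-less (tree)
# subgraph the single maximal-clearance root node is the source -- the
# diameter path exists for the width profile only, and using it as a source
# set would zero out the largest protrusion.
subgraph_heights <- function(subgraph, rp = root_path(subgraph)) {
  g <- subgraph$graph
  edges <- g$edges[subgraph$edge_ids, ]
  lg <- local_edge_graph(edges)
  roots <- if (rp$has_bridges) rp$vertex_ids else rp$root_id
  src <- match(roots, lg$vids)
  keep <- !is.na(src)
  src <- src[keep]
  cl <- g$vertices$clearance[roots[keep]]
  res <- .dijkstra_cpp(length(lg$vids), lg$ei, lg$ej, lg$w,
                       as.integer(src), -cl)
  setNames(res$dist[-1], lg$vids)
}

# local integer-id edge list for a subgraph edge table
local_edge_graph <- function(edges) {
  e <- edges[!is.na(edges$v2), ]
  vids <- sort(unique(c(e$v1, e$v2)))
  list(vids = vids,
       ei = match(e$v1, vids), ej = match(e$v2, vids),
       w = pmax(e$length, 0))
}

# arc position along the owning boundary of a tangency point
tangency_arc <- function(sites, site_id, tx, ty) {
  arc <- rep(NA_real_, length(site_id))
  st <- sites$type[site_id]
  pt <- which(st == "point")
  if (length(pt)) arc[pt] <- sites$arc0[site_id[pt]]
  seg <- which(st == "segment")
  if (length(seg)) {
    s <- site_id[seg]
    dx <- sites$x2[s] - sites$x1[s]; dy <- sites$y2[s] - sites$y1[s]
    len <- sqrt(dx^2 + dy^2)
    t <- ((tx[seg] - sites$x1[s]) * dx + (ty[seg] - sites$y1[s]) * dy) / len
    arc[seg] <- sites$arc0[s] + pmin(pmax(t, 0), len)
  }
  arc
}

# index of the circularly-nearest value in sorted `pos` for each `q`
nearest_circular <- function(pos, q, period) {
  n <- length(pos)
  i <- findInterval(q, pos)
  lo <- ifelse(i == 0L, n, i)
  hi <- ifelse(i == n, 1L, i + 1L)
  dlo <- pmin(abs(q - pos[lo]), period - abs(q - pos[lo]))
  dhi <- pmin(abs(q - pos[hi]), period - abs(q - pos[hi]))
  ifelse(dlo <= dhi, lo, hi)
}

#' The 20 per-side boundary metrics
#'
#' Computes, for one (boundary, side) subgraph: width-profile mean, SD,
#' third and fourth central moments, min, max (rows 1-6); boundary-profile
#' mean, SD, max (rows 7-9); area under the boundary profile above its 0th /
#' 25th / 50th / 75th quantile and the number of maximal runs above each
#' quantile (rows 10-17; for the 0th quantile, runs attaining the minimum);
#' enclosed area and perimeter of the boundary (rows 18-19); and the
#' exterior flag (row 20, 1 = exterior).
#'
#' @param subgraph a `shape_subgraph`.
#' @return Named numeric vector of length 20.
#' @export
side_features <- function(subgraph) {
  g <- subgraph$graph
  bid <- subgraph$boundary_id
  brow <- match(bid, g$boundaries$boundary_id)
  rp <- root_path(subgraph)
  wp <- width_profile(subgraph, rp)
  bp <- boundary_profile(subgraph, rp)
  r <- wp$radius
  h <- bp$height
  arc <- bp$arc
  per <- g$boundaries$perimeter[brow]
  qs <- quantile(h, c(0, 0.25, 0.5, 0.75), names = FALSE, type = 7)
  auc <- map_dbl(qs, function(q) trapezoid_auc(arc, pmax(h - q, 0), per))
  crossings <- c(
    run_count(h <= qs[1] + 1e-9),
    run_count(h > qs[2]),
    run_count(h > qs[3]),
    run_count(h > qs[4])
  )
  c(width_mean = mean(r),
    width_sd = if (length(r) > 1) sd(r) else 0,
    width_m3 = mean((r - mean(r))^3),
    width_m4 = mean((r - mean(r))^4),
    width_min = min(r),
    width_max = max(r),
    bnd_mean = mean(h),
    bnd_sd = if (length(h) > 1) sd(h) else 0,
    bnd_max = max(h),
    auc_q0 = auc[1], cross_q0 = crossings[1],
    auc_q25 = auc[2], cross_q25 = crossings[2],
    auc_q50 = auc[3], cross_q50 = crossings[3],
    auc_q75 = auc[4], cross_q75 = crossings[4],
    area = g$boundaries$area[brow],
    perimeter = per,
    exterior = as.numeric(g$boundaries$kind[brow] == "exterior"))
}

# trapezoid integral over a cyclic profile (closing segment included)
trapezoid_auc <- function(arc, y, period) {
  n <- length(arc)
  if (n < 2) return(0)
  base <- sum(diff(arc) * (y[-n] + y[-1]) / 2)
  base + (period - arc[n] + arc[1]) * (y[n] + y[1]) / 2
}

# number of maximal TRUE runs, treating the sequence as cyclic
run_count <- function(flag) {
  n <- length(flag)
  if (!any(flag)) return(0L)
  if (all(flag)) return(1L)
  starts <- sum(flag & !flag[c(n, seq_len(n - 1L))])
  as.integer(starts)
}

#' The 40-metric feature vector of one boundary
#'
#' Concatenates the 20 in-graph metrics and the 20 out-graph metrics of a
#' boundary (see [side_features()] for the per-side order). A missing side
#' (degenerate subgraph with no edges) yields zeros for that side's 20
#' entries, with a warning.
#'
#' @param graph an annotated `shape_graph`.
#' @param boundary_id which boundary.
#' @return Named numeric vector of length 40 (`in_*` then `out_*`).
#' @export
boundary_features <- function(graph, boundary_id) {
  sides <- c("in", "out")
  out <- vector("list", 2)
  for (k in 1:2) {
    sg <- subgraph_of(graph, boundary_id, sides[k])
    if (!length(sg$edge_ids)) {
      warn(sprintf("boundary %d has no %s-side subgraph; zero sentinel used",
                   boundary_id, sides[k]))
      v <- setNames(numeric(20), names(side_features_template()))
    } else {
      v <- side_features(sg)
    }
    names(v) <- paste0(sides[k], "_", names(v))
    out[[k]] <- v
  }
  c(out[[1]], out[[2]])
}

side_features_template <- function() {
  setNames(numeric(20),
           c("width_mean", "width_sd", "width_m3", "width_m4", "width_min",
             "width_max", "bnd_mean", "bnd_sd", "bnd_max",
             "auc_q0", "cross_q0", "auc_q25", "cross_q25",
             "auc_q50", "cross_q50", "auc_q75", "cross_q75",
             "area", "perimeter", "exterior"))
}

#' Names of the 40 per-boundary feature columns
#' @return Character vector of length 40 (`in_*` then `out_*`).
#' @export
feature_names <- function() {
  c(paste0("in_", names(side_features_template())),
    paste0("out_", names(side_features_template())))
}
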