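#' Export a shape graph to GraphML
#'
#' Vertex attributes: x, y, clearance, side, role (when annotated); edge
#' attributes: length, curve kind, generating boundary ids.
#'
#' @param graph a `shape_graph`.
#' @param path output `.graphml` path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  v <- graph$vertices
  e <- graph$edges[!is.na(graph$edges$v2), ]
  b1 <- graph$sites$boundary_id[e$site1]
  b2 <- graph$sites$boundary_id[e$site2]
  doc <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  keys <- list(
    c("vx", "node", "x", "double"), c("vy", "node", "y", "double"),
    c("vc", "node", "clearance", "double"),
    c("vs", "node", "side", "string"), c("vr", "node", "role", "string"),
    c("el", "edge", "length", "double"),
    c("ek", "edge", "curve_kind", "string"),
    c("eb1", "edge", "boundary1", "int"),
    c("eb2", "edge", "boundary2", "int"),
    c("es", "edge", "side", "string"))
  for (k in keys) {
    xml2::xml_add_child(doc, "key", id = k[1], `for` = k[2],
                        attr.name = k[3], attr.type = k[4])
  }
  gr <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "undirected")
  has_side <- !is.null(v$side)
  for (i in seq_len(nrow(v))) {
    nd <- xml2::xml_add_child(gr, "node", id = paste0("n", v$vertex_id[i]))
    xml2::xml_add_child(nd, "data", key = "vx", as.character(v$x[i]))
    xml2::xml_add_child(nd, "data", key = "vy", as.character(v$y[i]))
    xml2::xml_add_child(nd, "data", key = "vc", as.character(v$clearance[i]))
    if (has_side) {
      xml2::xml_add_child(nd, "data", key = "vs", v$side[i])
      xml2::xml_add_child(nd, "data", key = "vr", v$role[i])
    }
  }
  for (i in seq_len(nrow(e))) {
    ed <- xml2::xml_add_child(gr, "edge",
                              source = paste0("n", e$v1[i]),
                              target = paste0("n", e$v2[i]))
    xml2::xml_add_child(ed, "data", key = "el", as.character(e$length[i]))
    xml2::xml_add_child(ed, "data", key = "ek", e$curve_kind[i])
    xml2::xml_add_child(ed, "data", key = "eb1", as.character(b1[i]))
    xml2::xml_add_child(ed, "data", key = "eb2", as.character(b2[i]))
    if (!is.null(e$side)) xml2::xml_add_child(ed, "data", key = "es", e$side[i])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Export a shape graph as a flat CSV pair
#'
#' Writes `<stem>_vertices.csv` and `<stem>_edges.csv`.
#'
#' @param graph a `shape_graph`.
#' @param stem path stem (no extension).
#' @return The two paths, invisibly.
#' @export
write_graph_csv <- function(graph, stem) {
  vp <- paste0(stem, "_vertices.csv")
  ep <- paste0(stem, "_edges.csv")
  v <- graph$vertices
  v$equidistant <- NULL
  write.csv(v, vp, row.names = FALSE)
  e <- graph$edges
  e$boundary1 <- graph$sites$boundary_id[e$site1]
  e$boundary2 <- graph$sites$boundary_id[e$site2]
  write.csv(e, ep, row.names = FALSE)
  invisible(c(vp, ep))
}

#' Export boundaries to CSV (long format)
#'
#' One row per vertex: boundary_id, kind, owner, vertex index, x, y.
#'
#' @param boundaries a `shape_boundaries` tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_boundaries_csv <- function(boundaries, path) {
  rows <- pmap(list(boundaries$boundary_id, boundaries$kind,
                    boundaries$owner, boundaries$points),
               function(id, kind, owner, p) {
    tibble(boundary_id = id, kind = kind, owner = owner,
           vertex = seq_len(nrow(p)), x = p[, 1], y = p[, 2])
  })
  write.csv(list_rbind(rows), path, row.names = FALSE)
  invisible(path)
}

#' Export boundaries as GeoJSON polygons
#'
#' Each boundary becomes one Polygon feature with `boundary_id`, `kind`,
#' `owner`, `area`, `perimeter` properties (rings closed explicitly).
#'
#' @param boundaries a `shape_boundaries` tibble.
#' @param path output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_boundaries_geojson <- function(boundaries, path) {
  feats <- pmap(list(boundaries$boundary_id, boundaries$kind,
                     boundaries$owner, boundaries$area,
                     boundaries$perimeter, boundaries$points),
                function(id, kind, owner, area, per, p) {
    ring <- rbind(p, p[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(boundary_id = id, kind = kind, owner = owner,
                           area = area, perimeter = per),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                           function(i) c(ring[i, 1], ring[i, 2])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
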