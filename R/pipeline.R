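#' Extract the per-boundary feature table of one image
#'
#' Runs the full shape-to-graph pipeline on a segmented image: boundary
#' tracing (half-pixel convention for binary masks, quarter-pixel convention
#' for label images), generalized Voronoi graph construction bounded by the
#' image frame, in/out annotation, and the 40 per-boundary metrics.
#'
#' @param image a [raster_image()] (binary or label mode).
#' @param image_id identifier copied into the output (default `"image"`).
#' @param min_hole_area,min_object_area preprocessing thresholds for binary
#'   images (`NULL` disables preprocessing).
#' @param shift anti-crossing separation for binary tracing, px.
#' @param keep_graph also return the annotated graph (attribute `"graph"`).
#' @return A tibble with one row per boundary: `image_id`, `boundary_id`,
#'   `kind`, `owner`, then the 40 feature columns ([feature_names()]).
#' @export
extract_features <- function(image, image_id = "image",
                             min_hole_area = NULL, min_object_area = NULL,
                             shift = 0.05, keep_graph = FALSE) {
  stopifnot(inherits(image, "raster_image"))
  if (image$mode == "binary") {
    if (!is.null(min_hole_area) || !is.null(min_object_area)) {
      image <- preprocess_binary(image,
                                 min_hole_area = min_hole_area %||% 0,
                                 min_object_area = min_object_area %||% 0)
    }
    b <- trace_binary_boundaries(image, shift = shift)
  } else {
    b <- trace_label_boundaries(image)
  }
  if (!nrow(b)) {
    out <- bind_cols(tibble(image_id = character(), boundary_id = integer(),
                            kind = character(), owner = integer()),
                     as_tibble(matrix(numeric(), 0, 40,
                                      dimnames = list(NULL, feature_names()))))
    return(out)
  }
  g <- annotate_graph(build_shape_graph(b))
  feats <- map(b$boundary_id, function(bid) {
    as_tibble(as.list(boundary_features(g, bid)))
  })
  out <- bind_cols(
    tibble(image_id = image_id, boundary_id = b$boundary_id,
           kind = b$kind, owner = b$owner),
    list_rbind(feats))
  if (keep_graph) attr(out, "graph") <- g
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract features for a set of images
#'
#' @param images named list of [raster_image()] objects (names become
#'   `image_id`s).
#' @param ... passed to [extract_features()].
#' @return Row-bound feature tibble across images.
#' @export
extract_features_set <- function(images, ...) {
  if (is.null(names(images))) {
    names(images) <- sprintf("image_%03d", seq_along(images))
  }
  list_rbind(imap(images, function(img, id) {
    extract_features(img, image_id = id, ...)
  }))
}
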