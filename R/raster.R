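#' Create a raster image object
#'
#' A thin container for segmented images: an integer matrix of pixel values
#' (rows = y, columns = x) together with its mode. In `"binary"` mode values
#' are 0 (background) and 1 (foreground); in `"label"` mode each object
#' carries its own positive integer label and 0 is background.
#'
#' Pixel centres sit at integer coordinates (`x = col - 1`, `y = row - 1`),
#' so the image occupies `[-0.5, W - 0.5] x [-0.5, H - 0.5]` and the
#' half-pixel borders between pixels fall on half-integers.
#'
#' @param values integer matrix of pixel values.
#' @param mode `"binary"` or `"label"`.
#' @return A `raster_image` object.
#' @export
raster_image <- function(values, mode = c("binary", "label")) {
  mode <- match.arg(mode)
  if (!is.matrix(values)) abort("`values` must be a matrix")
  storage.mode(values) <- "integer"
  if (anyNA(values) || any(values < 0L)) {
    abort("raster values must be non-negative integers")
  }
  if (mode == "binary" && any(values > 1L)) {
    abort("binary mode requires values in {0, 1}", class = "shapegraph_mode_error")
  }
  structure(list(values = values, mode = mode), class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("<raster_image> %d x %d pixels, mode '%s', %d foreground px\n",
              nrow(x$values), ncol(x$values), x$mode, sum(x$values > 0L)))
  invisible(x)
}

#' @export
dim.raster_image <- function(x) dim(x$values)

#' Read a mask or label image from PNG or TIFF
#'
#' Binary masks may be stored as 0/1 or 0/255 (any non-zero value is
#' foreground); label images should be 8- or 16-bit integer TIFF (or PNG),
#' with one label per object.
#'
#' @param path file path (`.png`, `.tif`, `.tiff`).
#' @param mode `"binary"` or `"label"`.
#' @return A [raster_image()].
#' @export
read_raster <- function(path, mode = c("binary", "label")) {
  mode <- match.arg(mode)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path, as.is = TRUE),
    abort(sprintf("unsupported image format '%s'", ext))
  )
  if (length(dim(img)) == 3L) img <- img[, , 1L]  # first channel
  if (is.double(img)) {
    # readPNG / readTIFF may rescale to [0, 1]; undo for integer content
    if (max(img) <= 1) img <- img * ifelse(mode == "binary", 1, 65535)
    img <- round(img)
  }
  m <- matrix(as.integer(img), nrow = nrow(img))
  if (mode == "binary") m[m != 0L] <- 1L
  raster_image(m, mode)
}

#' Write a raster image to PNG or TIFF
#'
#' @param image a [raster_image()].
#' @param path output path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_raster <- function(image, path) {
  stopifnot(inherits(image, "raster_image"))
  ext <- tolower(tools::file_ext(path))
  v <- image$values
  if (ext == "png") {
    png::writePNG(v / max(1L, max(v)), path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(v / 65535, path, bits.per.sample = 16L)
  } else {
    abort(sprintf("unsupported image format '%s'", ext))
  }
  invisible(path)
}

#' Image frame rectangle
#'
#' The rectangle `[-0.5, W-0.5] x [-0.5, H-0.5]` bounding the pixel grid;
#' used as the outermost boundary of the shape graph.
#'
#' @param image a [raster_image()] (or an integer matrix).
#' @return Numeric `c(xmin, ymin, xmax, ymax)`.
#' @export
image_frame <- function(image) {
  d <- if (inherits(image, "raster_image")) dim(image$values) else dim(image)
  c(xmin = -0.5, ymin = -0.5, xmax = d[2] - 0.5, ymax = d[1] - 0.5)
}

# connected-component labelling (internal); conn = 4 or 8
label_components <- function(mask, conn = 8L) {
  .cc_label_cpp(mask, as.integer(conn))
}

#' Fill small holes and remove small objects in a binary image
#'
#' Holes (4-connected background components not touching the image border)
#' with area strictly below `min_hole_area` are filled; foreground components
#' (8-connected) with area strictly below `min_object_area` are removed.
#' The defaults reproduce a typical experiment-like setting (fill holes
#' below 21 px, drop debris below 101 px); both are plain parameters and
#' should be tuned to the data.
#'
#' @param image a binary [raster_image()].
#' @param min_hole_area holes strictly smaller than this many px^2 are filled.
#' @param min_object_area objects strictly smaller than this are removed.
#' @return The filtered binary [raster_image()].
#' @export
preprocess_binary <- function(image, min_hole_area = 21, min_object_area = 101) {
  stopifnot(inherits(image, "raster_image"))
  if (image$mode != "binary") {
    abort("preprocess_binary() requires a binary image",
          class = "shapegraph_mode_error")
  }
  if (min_hole_area < 0 || min_object_area < 0) abort("thresholds must be >= 0")
  v <- image$values
  if (min_hole_area > 0) {
    bg <- label_components(1L - v, conn = 4L)
    if (attr(bg, "n") > 0) {
      border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
      sizes <- tabulate(bg, nbins = attr(bg, "n"))
      fill <- setdiff(which(sizes < min_hole_area), border)
      if (length(fill)) v[bg %in% fill] <- 1L
    }
  }
  if (min_object_area > 0) {
    fgl <- label_components(v, conn = 8L)
    if (attr(fgl, "n") > 0) {
      sizes <- tabulate(fgl, nbins = attr(fgl, "n"))
      drop <- which(sizes < min_object_area)
      if (length(drop)) v[fgl %in% drop] <- 0L
    }
  }
  raster_image(v, "binary")
}
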