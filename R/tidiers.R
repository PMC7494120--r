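#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a shape graph into a vertex tibble
#'
#' @param x a `shape_graph`.
#' @param what `"vertices"` or `"edges"`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.shape_graph <- function(x, what = c("vertices", "edges"), ...) {
  what <- match.arg(what)
  if (what == "vertices") {
    v <- x$vertices
    v$equidistant <- NULL
    v
  } else {
    e <- x$edges
    e$boundary1 <- x$sites$boundary_id[e$site1]
    e$boundary2 <- x$sites$boundary_id[e$site2]
    e
  }
}

#' One-row graph summary
#'
#' @param x a `shape_graph`.
#' @param ... unused.
#' @return A one-row tibble: vertex/edge/site/boundary counts, max clearance,
#'   total edge length by side when annotated.
#' @export
glance.shape_graph <- function(x, ...) {
  out <- tibble(
    n_vertices = nrow(x$vertices),
    n_edges = nrow(x$edges),
    n_sites = nrow(x$sites),
    n_boundaries = if (is.null(x$boundaries)) NA_integer_
                   else nrow(x$boundaries),
    max_clearance = max(x$vertices$clearance))
  if (!is.null(x$edges$side)) {
    len <- tapply(x$edges$length, x$edges$side, sum)
    out$length_in <- unname(len["in"])
    out$length_out <- unname(len["out"])
  }
  out
}

#' Tidy a boundary-type regression
#'
#' @param x a `type_regression`.
#' @param ... unused.
#' @return A tibble with one row per (parameter, term) coefficient.
#' @export
tidy.type_regression <- function(x, ...) {
  list_rbind(imap(x$coefficients, function(b, nm) {
    tibble(parameter = nm,
           term = c("(Intercept)", paste0("type_", seq_len(length(b) - 1))),
           estimate = as.numeric(b))
  }))
}

#' One-row regression summary
#'
#' @param x a `type_regression`.
#' @param ... unused.
#' @return A one-row tibble per parameter with leave-one-out MAE and Pearson
#'   correlation.
#' @export
glance.type_regression <- function(x, ...) {
  tibble(parameter = names(x$mae),
         mae = as.numeric(x$mae),
         pearson = as.numeric(x$pearson),
         n = x$n)
}
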