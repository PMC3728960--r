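#' Define a rectangular (optionally polygon-bounded) study region
#'
#' A region is the two-dimensional space available to the collared animals.
#' Coordinates are planar/projected meters throughout; latitude/longitude is
#' not supported because all distances are Euclidean.
#'
#' @param xmin,ymin,xmax,ymax Bounding box, meters. `xmax > xmin`, `ymax > ymin`.
#' @param boundary Optional two-column matrix (or data frame) of polygon
#'   vertices `(x, y)` in meters describing a simple (non-self-intersecting)
#'   boundary lying within the bounding box. When present, unit centers and
#'   simulated locations are restricted to the polygon.
#'
#' @return An object of class `nbrsf_region`.
#' @examples
#' region(0, 0, 9000, 9000)
#' @export
region <- function(xmin, ymin, xmax, ymax, boundary = NULL) {
  stopifnot(is.numeric(xmin), is.numeric(ymin), is.numeric(xmax), is.numeric(ymax))
  if (!(xmax > xmin && ymax > ymin)) {
    abort("invalid region: need xmax > xmin and ymax > ymin", class = "nbrsf_region_error")
  }
  if (!is.null(boundary)) {
    boundary <- as.matrix(boundary)[, 1:2, drop = FALSE]
    storage.mode(boundary) <- "double"
    if (nrow(boundary) < 3L) {
      abort("polygon boundary needs at least 3 vertices", class = "nbrsf_region_error")
    }
    if (any(boundary[, 1] < xmin | boundary[, 1] > xmax |
            boundary[, 2] < ymin | boundary[, 2] > ymax)) {
      abort("polygon boundary must lie within the bounding box", class = "nbrsf_region_error")
    }
  }
  structure(
    list(xmin = as.numeric(xmin), ymin = as.numeric(ymin),
         xmax = as.numeric(xmax), ymax = as.numeric(ymax),
         boundary = boundary),
    class = "nbrsf_region"
  )
}

#' @export
print.nbrsf_region <- function(x, ...) {
  cat(sprintf("<nbrsf_region> [%g, %g] x [%g, %g] m%s\n",
              x$xmin, x$xmax, x$ymin, x$ymax,
              if (is.null(x$boundary)) "" else
                sprintf(", polygon boundary (%d vertices)", nrow(x$boundary))))
  invisible(x)
}

# TRUE for points inside the region (box, then polygon if present)
region_contains <- function(region, x, y) {
  inside <- x >= region$xmin & x <= region$xmax &
    y >= region$ymin & y <= region$ymax
  if (!is.null(region$boundary) && any(inside)) {
    inside[inside] <- mgcv::in.out(region$boundary, cbind(x[inside], y[inside]))
  }
  inside
}

region_width <- function(region) region$xmax - region$xmin
region_height <- function(region) region$ymax - region$ymin

as_region <- function(x) {
  if (inherits(x, "nbrsf_region")) return(x)
  if (is.numeric(x) && length(x) == 4L) {
    return(region(x[[1]], x[[2]], x[[3]], x[[4]]))
  }
  abort("cannot interpret input as a region; use region()", class = "nbrsf_region_error")
}
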