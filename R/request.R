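#' Cutout requests
#'
#' A cutout request names an axis-aligned, half-open box
#' `[x0,x1) x [y0,y1) x [z0,z1)` of a channel or data-instance resource at one
#' resolution level.  All coordinates are 0-based voxel indices at that
#' resolution; ranges are given in X, Y, Z order.
#'
#' @param resource A channel or data-instance `vk_resource`.
#' @param x,y,z Length-2 integer vectors `c(start, stop)`, half-open.
#' @param resolution Resolution level, 0-based.
#' @return An object of class `vk_request`.
#' @examples
#' fr <- coordinate_frame(c(64, 64, 16))
#' ch <- channel_resource("c", "e", "ch", frame = fr)
#' req <- cutout_request(ch, c(0, 32), c(0, 32), c(0, 16))
#' request_shape(req)
#' @export
cutout_request <- function(resource, x, y, z, resolution = 0L) {
  if (!inherits(resource, "vk_resource") ||
      !resource$kind %in% c("channel", "data_instance"))
    vk_stop("usage", "cutouts address channel or data_instance resources")
  rng <- function(v, axis) {
    v <- as.integer(v)
    if (length(v) != 2L || anyNA(v))
      vk_stop("usage", "%s range must be two integers (start, stop)", axis)
    v
  }
  structure(
    list(resource = resource, resolution = as.integer(resolution),
         x = rng(x, "x"), y = rng(y, "y"), z = rng(z, "z")),
    class = "vk_request"
  )
}

#' @export
print.vk_request <- function(x, ...) {
  cat(sprintf("<vk_request> %s res %d [%d,%d)x[%d,%d)x[%d,%d)\n",
              resource_uri(x$resource), x$resolution,
              x$x[1], x$x[2], x$y[1], x$y[2], x$z[1], x$z[2]))
  invisible(x)
}

#' Shape of the requested box
#' @param request A `vk_request`.
#' @return Integer vector `c(nx, ny, nz)`.
#' @export
request_shape <- function(request) {
  as.integer(c(request$x[2] - request$x[1],
               request$y[2] - request$y[1],
               request$z[2] - request$z[1]))
}

#' Validate a cutout request against a coordinate frame
#'
#' Checks that every range is non-empty, lies within the frame's extents at
#' the requested resolution, and that the resolution level exists.  Returns
#' the request unchanged (validation is idempotent); failures raise classed
#' errors: `vk_empty_range_error`, `vk_bounds_error` (naming the offending
#' axis), or `vk_resolution_error`.
#'
#' @param request A `vk_request`.
#' @param frame The [coordinate_frame()] of the request's resource; defaults
#'   to the frame attached to the resource.
#' @return The validated request, invisibly equal to the input.
#' @export
validate_request <- function(request, frame = request$resource$frame) {
  if (is.null(frame))
    vk_stop("usage", "no coordinate frame available to validate against")
  check_resolution(frame, request$resolution)
  ext <- extents_at(frame, request$resolution)
  axes <- c("x", "y", "z")
  for (a in seq_along(axes)) {
    r <- request[[axes[a]]]
    if (r[1] >= r[2])
      vk_stop("empty_range", "empty %s range [%d,%d)", axes[a], r[1], r[2])
    if (r[1] < 0L || r[2] > ext[a])
      vk_stop("bounds", "%s range [%d,%d) outside extent [0,%d) at resolution %d",
              axes[a], r[1], r[2], ext[a], request$resolution,
              data = list(axis = axes[a]))
  }
  request
}
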