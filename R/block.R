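#' Volume blocks
#'
#' A volume block is a dense 3D array tied to the cutout request that produced
#' it: the universal payload between remotes and services.  The array is
#' dimensioned `(X, Y, Z)` and indexed `[x, y, z]`, so its linearized memory
#' (x fastest-varying) matches C-order `(z, y, x)` serialization byte for
#' byte.
#'
#' @param data A 3D array whose shape equals the request's box shape.
#' @param request The `vk_request` the voxels answer.
#' @return An object of class `vk_block`.
#' @export
volume_block <- function(data, request) {
  shape <- request_shape(request)
  if (length(dim(data)) != 3L)
    vk_stop("shape", "volume data must be a 3D array")
  if (!all(dim(data) == shape))
    vk_stop("shape", "data shape (%s) does not match request shape (%s)",
            paste(dim(data), collapse = "x"), paste(shape, collapse = "x"))
  dtype <- request$resource$dtype
  if (!is.null(dtype)) data <- coerce_voxels(data, dtype)
  structure(list(data = data, request = request, dtype = dtype),
            class = "vk_block")
}

#' @export
print.vk_block <- function(x, ...) {
  cat(sprintf("<vk_block> %s %s, range [%s, %s]\n",
              paste(dim(x$data), collapse = "x"), x$dtype %||% "untyped",
              format(min(x$data)), format(max(x$data))))
  invisible(x)
}

#' @export
as.array.vk_block <- function(x, ...) x$data

# physical voxel size of the block, from the resource frame at the request's
# resolution; NULL if the resource has no frame
block_voxel_size <- function(block) {
  fr <- block$request$resource$frame
  if (is.null(fr)) return(NULL)
  voxel_size_at(fr, block$request$resolution)
}
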