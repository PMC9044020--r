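# Voxel dtypes.  Volumes are unsigned 8/16-bit intensity (image channels) or
# unsigned 64-bit labels (annotation channels).  R has no native unsigned
# integer types, so:
#   uint8, uint16 -> R integer arrays
#   uint64        -> R double arrays (exact for values below 2^53, far above
#                    any label id these tools handle)
# Serialization is always little-endian C order with x fastest-varying.

.vk_dtypes <- list(
  uint8  = list(bytes = 1L, max = 255,        storage = "integer"),
  uint16 = list(bytes = 2L, max = 65535,      storage = "integer"),
  uint64 = list(bytes = 8L, max = 2^53,       storage = "double")
)

#' Supported voxel dtypes
#' @return Character vector of dtype names.
#' @export
vk_dtypes <- function() names(.vk_dtypes)

dtype_info <- function(dtype) {
  info <- .vk_dtypes[[dtype]]
  if (is.null(info)) vk_stop("dtype", "unsupported dtype '%s'", dtype)
  info
}

dtype_bytes <- function(dtype) dtype_info(dtype)$bytes

# zero-filled array with the storage mode matching `dtype`
new_volume_array <- function(shape, dtype) {
  info <- dtype_info(dtype)
  zero <- if (info$storage == "integer") 0L else 0
  array(zero, dim = as.integer(shape))
}

# coerce values (vector or array) into the dtype's storage mode, rejecting
# out-of-range or fractional input
coerce_voxels <- function(values, dtype) {
  info <- dtype_info(dtype)
  v <- as.vector(values)
  if (any(v < 0) || any(v > info$max))
    vk_stop("dtype", "values out of range for %s", dtype)
  if (info$storage == "integer") {
    out <- as.integer(v)
    if (any(out != v)) vk_stop("dtype", "non-integer values for %s", dtype)
  } else {
    out <- as.double(v)
    if (any(out != floor(out))) vk_stop("dtype", "non-integer values for %s", dtype)
  }
  if (!is.null(dim(values))) dim(out) <- dim(values)
  out
}

# dense array (x fastest) -> little-endian raw vector
encode_voxels <- function(values, dtype) {
  info <- dtype_info(dtype)
  v <- as.vector(values)
  if (info$bytes <= 2L) {
    writeBin(as.integer(v), raw(), size = info$bytes, endian = "little")
  } else {
    # uint64: manual little-endian byte split of exact doubles
    v <- as.double(v)
    out <- raw(8L * length(v))
    if (length(v)) {
      for (k in 0:7) {
        out[seq_along(v) * 8L - 7L + k] <- as.raw((v %/% (256^k)) %% 256)
      }
    }
    out
  }
}

# little-endian raw vector -> vector in the dtype's storage mode
decode_voxels <- function(bytes, dtype) {
  info <- dtype_info(dtype)
  if (length(bytes) %% info$bytes != 0L)
    vk_stop("shape", "byte payload length %d is not a multiple of %d (dtype %s)",
            length(bytes), info$bytes, dtype)
  n <- length(bytes) %/% info$bytes
  if (info$bytes <= 2L) {
    readBin(bytes, "integer", n = n, size = info$bytes,
            signed = FALSE, endian = "little")
  } else {
    if (n == 0L) return(double(0))
    m <- matrix(as.integer(bytes), nrow = 8L)
    as.double(colSums(m * 256^(0:7)))
  }
}

# raw payload -> array of given shape, checking length
decode_volume <- function(bytes, shape, dtype) {
  v <- decode_voxels(bytes, dtype)
  if (length(v) != prod(shape))
    vk_stop("shape", "payload has %d voxels, expected %d", length(v), prod(shape))
  array(v, dim = as.integer(shape))
}
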