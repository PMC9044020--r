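#' Wavefront OBJ mesh export
#'
#' Writes `v x y z` lines followed by `f a b c` lines (1-based indices),
#' coordinates formatted to 6 significant digits.  An empty mesh writes an
#' empty file.  [read_obj()] is the matching reader: triangles round-trip
#' exactly, vertices to formatting precision.
#'
#' @param mesh A `vk_mesh`.
#' @param destination File path or writable connection.
#' @return The destination, invisibly.
#' @export
write_obj <- function(mesh, destination) {
  v <- mesh$vertices
  f <- mesh$triangles
  lines <- character(0)
  if (nrow(v))
    lines <- sprintf("v %.6g %.6g %.6g", v[, 1], v[, 2], v[, 3])
  if (nrow(f))
    lines <- c(lines, sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]))
  writeLines(lines, destination)
  invisible(destination)
}

#' @rdname write_obj
#' @param source File path or connection holding OBJ text.
#' @return `read_obj()` returns a `vk_mesh` (label `NA`).
#' @export
read_obj <- function(source) {
  lines <- readLines(source, warn = FALSE)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  verts <- if (length(vl)) {
    do.call(rbind, lapply(strsplit(vl, "[[:space:]]+"), function(p)
      as.numeric(p[2:4])))
  } else matrix(numeric(0), 0, 3)
  tris <- if (length(fl)) {
    do.call(rbind, lapply(strsplit(fl, "[[:space:]]+"), function(p)
      as.integer(sub("/.*", "", p[2:4]))))
  } else matrix(integer(0), 0, 3)
  new_mesh(verts, tris, NA, NULL)
}

#' Neuroglancer legacy precomputed mesh fragment
#'
#' The single-resolution mesh fragment dialect: a little-endian `uint32`
#' vertex count, then `float32` (x, y, z) triples in nanometers, then
#' `uint32` triangle index triples (0-based).  Total length is exactly
#' `4 + 12 V + 12 T` bytes.  [read_precomputed()] inverts it bit-exactly for
#' float32-representable vertices.
#'
#' @inheritParams write_obj
#' @return `write_precomputed()` returns the destination invisibly;
#'   `precomputed_bytes()` returns the fragment as a raw vector.
#' @export
write_precomputed <- function(mesh, destination) {
  writeBin(precomputed_bytes(mesh), destination)
  invisible(destination)
}

#' @rdname write_precomputed
#' @export
precomputed_bytes <- function(mesh) {
  nv <- nrow(mesh$vertices)
  if (nv >= 2^31)
    vk_stop("overflow", "vertex count %d exceeds the uint32 fragment limit", nv)
  head <- writeBin(as.integer(nv), raw(), size = 4L, endian = "little")
  vbytes <- writeBin(as.numeric(t(mesh$vertices)), raw(), size = 4L,
                     endian = "little")
  tbytes <- writeBin(as.integer(t(mesh$triangles) - 1L), raw(), size = 4L,
                     endian = "little")
  c(head, vbytes, tbytes)
}

#' @rdname write_precomputed
#' @param source File path holding a precomputed fragment.
#' @return `read_precomputed()` returns a `vk_mesh` (label `NA`).
#' @export
read_precomputed <- function(source) {
  bytes <- if (is.raw(source)) source
           else readBin(source, "raw", n = file.size(source))
  if (length(bytes) < 4L)
    vk_stop("shape", "precomputed fragment shorter than its header")
  nv <- readBin(bytes[1:4], "integer", size = 4L, endian = "little")
  need <- 4L + 12L * nv
  if (length(bytes) < need || (length(bytes) - need) %% 12L != 0L)
    vk_stop("shape", "precomputed fragment length %d inconsistent with %d vertices",
            length(bytes), nv)
  verts <- matrix(readBin(bytes[seq_len(12L * nv) + 4L], "double", n = 3L * nv,
                          size = 4L, endian = "little"),
                  ncol = 3L, byrow = TRUE)
  nt <- (length(bytes) - need) %/% 12L
  tris <- matrix(readBin(bytes[seq_len(12L * nt) + need], "integer", n = 3L * nt,
                         size = 4L, endian = "little"),
                 ncol = 3L, byrow = TRUE) + 1L
  new_mesh(verts, tris, NA, NULL)
}
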