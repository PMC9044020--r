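#' On-disk chunked-file remote
#'
#' A remote storing each resource as a directory of fixed-shape chunk files
#' plus one JSON metadata document.  The layout (a deliberately simple,
#' zarr-like dialect, specified exactly so other tools can read it) is:
#'
#' ```
#' root/collection/experiment/channel/meta.json
#' root/collection/experiment/channel/res{r}/{i}_{j}_{k}.bin
#' root/instance-name/meta.json                 (data instances)
#' ```
#'
#' Chunk files are raw little-endian voxels in C order (x fastest).  Chunks at
#' the volume boundary are stored truncated to the clipped shape; readers pad
#' them back to full chunk shape.  An absent chunk file is, by definition, an
#' all-zero chunk — writers delete files whose content becomes all zeros, so
#' writing a single voxel costs exactly one small file.
#'
#' @param root Root directory (created if missing).
#' @param chunks Default chunk shape for newly created resources.
#' @return A remote of class `vk_file_remote`.
#' @export
file_chunk_remote <- function(root, chunks = default_chunk_shape()) {
  dir.create(root, showWarnings = FALSE, recursive = TRUE)
  self <- new.env(parent = emptyenv())
  self$root <- normalizePath(root)
  self$default_chunks <- as_chunk_shape(chunks)
  class(self) <- c("vk_file_remote", "vk_remote")
  self
}

#' @export
remote_capabilities.vk_file_remote <- function(remote) {
  c("read", "write", "create", "list")
}

file_res_dir <- function(remote, resource) {
  file.path(remote$root, resource_path_of(resource))
}

resource_path_of <- function(resource) {
  if (is.character(resource)) {
    r <- parse_resource_uri(resource)
    resource_path(r)
  } else resource_path(resource)
}

#' @export
create_resource.vk_file_remote <- function(remote, resource,
                                           frame = resource$frame,
                                           chunks = remote$default_chunks) {
  if (!resource$kind %in% c("channel", "data_instance"))
    vk_stop("usage", "only channel and data_instance resources hold voxels")
  if (is.null(frame)) vk_stop("usage", "a coordinate frame is required")
  dir <- file_res_dir(remote, resource)
  meta_path <- file.path(dir, "meta.json")
  if (file.exists(meta_path))
    vk_stop("already_exists", "resource '%s' already exists", resource_uri(resource))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  resource$frame <- frame
  meta <- list(kind = resource$kind, path = resource$path,
               channel_kind = resource$channel_kind, dtype = resource$dtype,
               frame = frame_to_list(frame),
               chunks = as.integer(as_chunk_shape(chunks)))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA), meta_path)
  invisible(resource)
}

read_file_meta <- function(remote, resource) {
  dir <- file_res_dir(remote, resource)
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path))
    vk_stop("not_found", "unknown resource '%s'", as_resource_uri_any(resource))
  m <- jsonlite::fromJSON(paste(readLines(meta_path, warn = FALSE), collapse = ""))
  frame <- frame_from_list(m$frame)
  res <- if (m$kind == "data_instance") {
    data_instance_resource(m$path, m$channel_kind, m$dtype, frame)
  } else {
    channel_resource(m$path[1], m$path[2], m$path[3], m$channel_kind, m$dtype, frame)
  }
  list(resource = res, frame = frame, dtype = m$dtype,
       channel_kind = m$channel_kind, chunks = as_chunk_shape(m$chunks),
       dir = dir)
}

as_resource_uri_any <- function(resource) {
  if (is.character(resource)) resource else resource_uri(resource)
}

#' @export
get_metadata.vk_file_remote <- function(remote, resource) {
  m <- read_file_meta(remote, resource)
  m[c("resource", "frame", "dtype", "channel_kind", "chunks")]
}

chunk_file <- function(dir, resolution, i, j, k) {
  file.path(dir, sprintf("res%d", resolution), sprintf("%d_%d_%d.bin", i, j, k))
}

# stored (possibly truncated) shape of chunk (i,j,k)
stored_chunk_shape <- function(chunks, ijk, ext) {
  c0 <- ijk * chunks
  as.integer(pmin(c0 + chunks, ext) - c0)
}

# read chunk file, pad to full chunk shape; absent file -> zeros
read_chunk <- function(meta, resolution, ijk, ext) {
  chunks <- meta$chunks
  path <- chunk_file(meta$dir, resolution, ijk[1], ijk[2], ijk[3])
  full <- new_volume_array(chunks, meta$dtype)
  if (!file.exists(path)) return(full)
  sshape <- stored_chunk_shape(chunks, ijk, ext)
  bytes <- readBin(path, "raw", n = prod(sshape) * dtype_bytes(meta$dtype))
  stored <- decode_volume(bytes, sshape, meta$dtype)
  full[seq_len(sshape[1]), seq_len(sshape[2]), seq_len(sshape[3])] <- stored
  full
}

# write full-shape chunk array, truncating at volume extents; all-zero
# chunks are deleted to keep the absent-file <=> all-zero invariant
write_chunk <- function(meta, resolution, ijk, ext, full) {
  path <- chunk_file(meta$dir, resolution, ijk[1], ijk[2], ijk[3])
  sshape <- stored_chunk_shape(meta$chunks, ijk, ext)
  stored <- full[seq_len(sshape[1]), seq_len(sshape[2]), seq_len(sshape[3]), drop = FALSE]
  if (all(stored == 0)) {
    if (file.exists(path)) unlink(path)
    return(invisible())
  }
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  writeBin(encode_voxels(stored, meta$dtype), path)
  invisible()
}

#' @export
get_cutout.vk_file_remote <- function(remote, request, workers = 1L) {
  meta <- read_file_meta(remote, request$resource)
  validate_request(request, meta$frame)
  ext <- extents_at(meta$frame, request$resolution)
  request$resource <- meta$resource
  plan <- decompose(request, meta$chunks)
  fetch_one <- function(r) {
    read_chunk(meta, request$resolution, c(plan$i[r], plan$j[r], plan$k[r]), ext)
  }
  fetch_and_stitch(plan, fetch_one, workers)
}

#' @export
post_cutout.vk_file_remote <- function(remote, request, data) {
  meta <- read_file_meta(remote, request$resource)
  data <- check_write(meta, request, data)
  ext <- extents_at(meta$frame, request$resolution)
  request$resource <- meta$resource
  plan <- decompose(request, meta$chunks)
  for (r in seq_len(nrow(plan))) {
    ijk <- c(plan$i[r], plan$j[r], plan$k[r])
    full <- read_chunk(meta, request$resolution, ijk, ext)
    sx <- (plan$gx0[r] - ijk[1] * meta$chunks[1] + 1L):(plan$gx1[r] - ijk[1] * meta$chunks[1])
    sy <- (plan$gy0[r] - ijk[2] * meta$chunks[2] + 1L):(plan$gy1[r] - ijk[2] * meta$chunks[2])
    sz <- (plan$gz0[r] - ijk[3] * meta$chunks[3] + 1L):(plan$gz1[r] - ijk[3] * meta$chunks[3])
    full[sx, sy, sz] <- data[(plan$dx0[r] + 1L):plan$dx1[r],
                             (plan$dy0[r] + 1L):plan$dy1[r],
                             (plan$dz0[r] + 1L):plan$dz1[r]]
    write_chunk(meta, request$resolution, ijk, ext, full)
  }
  invisible(remote)
}

#' @export
list_resources.vk_file_remote <- function(remote, prefix = "") {
  metas <- list.files(remote$root, pattern = "^meta\\.json$", recursive = TRUE)
  paths <- dirname(metas)
  list_children(paths[paths != "."], prefix)
}
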