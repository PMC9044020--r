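#' In-memory remote
#'
#' A remote backed by dense arrays in the R session: the simplest
#' implementation of the remote trait and the reference against which the
#' chunked backends are tested.  Supports read, write, create and list.
#'
#' @param chunks Nominal chunk shape reported in metadata (consumed by the
#'   caching relay and by clients that decompose requests).
#' @return A remote of class `vk_memory_remote`.
#' @examples
#' rem <- memory_remote()
#' fr <- coordinate_frame(c(64, 64, 16))
#' ch <- channel_resource("c", "e", "img", frame = fr)
#' create_resource(rem, ch)
#' req <- cutout_request(ch, c(0, 8), c(0, 8), c(0, 8))
#' max(as.array(get_cutout(rem, req)))  # fresh resources read as zeros
#' @export
memory_remote <- function(chunks = default_chunk_shape()) {
  self <- new.env(parent = emptyenv())
  self$store <- new.env(parent = emptyenv())
  self$default_chunks <- as_chunk_shape(chunks)
  class(self) <- c("vk_memory_remote", "vk_remote")
  self
}

#' @export
print.vk_remote <- function(x, ...) {
  cat(sprintf("<%s> capabilities: %s\n", class(x)[1],
              paste(remote_capabilities(x), collapse = ", ")))
  invisible(x)
}

#' @export
remote_capabilities.vk_memory_remote <- function(remote) {
  c("read", "write", "create", "list")
}

#' @export
create_resource.vk_memory_remote <- function(remote, resource,
                                             frame = resource$frame,
                                             chunks = remote$default_chunks) {
  if (!resource$kind %in% c("channel", "data_instance"))
    vk_stop("usage", "only channel and data_instance resources hold voxels")
  if (is.null(frame)) vk_stop("usage", "a coordinate frame is required")
  uri <- resource_uri(resource)
  if (!is.null(remote$store[[uri]]))
    vk_stop("already_exists", "resource '%s' already exists", uri)
  resource$frame <- frame
  remote$store[[uri]] <- list(resource = resource, frame = frame,
                              chunks = as_chunk_shape(chunks),
                              levels = list())
  invisible(resource)
}

mem_entry <- function(remote, resource) {
  uri <- as_resource_uri(resource)
  entry <- remote$store[[uri]]
  if (is.null(entry)) vk_stop("not_found", "unknown resource '%s'", uri)
  entry
}

mem_level <- function(remote, resource, resolution) {
  uri <- as_resource_uri(resource)
  entry <- mem_entry(remote, uri)
  key <- paste0("res", resolution)
  if (is.null(entry$levels[[key]])) {
    ext <- extents_at(entry$frame, resolution)
    entry$levels[[key]] <- new_volume_array(ext, entry$resource$dtype)
    remote$store[[uri]] <- entry
  }
  entry$levels[[key]]
}

#' @export
get_metadata.vk_memory_remote <- function(remote, resource) {
  entry <- mem_entry(remote, resource)
  list(resource = entry$resource, frame = entry$frame,
       dtype = entry$resource$dtype, channel_kind = entry$resource$channel_kind,
       chunks = entry$chunks)
}

#' @export
get_cutout.vk_memory_remote <- function(remote, request, workers = 1L) {
  meta <- get_metadata(remote, request$resource)
  validate_request(request, meta$frame)
  arr <- mem_level(remote, request$resource, request$resolution)
  out <- arr[(request$x[1] + 1L):request$x[2],
             (request$y[1] + 1L):request$y[2],
             (request$z[1] + 1L):request$z[2], drop = FALSE]
  request$resource <- meta$resource
  volume_block(out, request)
}

#' @export
post_cutout.vk_memory_remote <- function(remote, request, data) {
  meta <- get_metadata(remote, request$resource)
  data <- check_write(meta, request, data)
  uri <- as_resource_uri(request$resource)
  arr <- mem_level(remote, uri, request$resolution)
  arr[(request$x[1] + 1L):request$x[2],
      (request$y[1] + 1L):request$y[2],
      (request$z[1] + 1L):request$z[2]] <- data
  entry <- remote$store[[uri]]
  entry$levels[[paste0("res", request$resolution)]] <- arr
  remote$store[[uri]] <- entry
  invisible(remote)
}

#' @export
list_resources.vk_memory_remote <- function(remote, prefix = "") {
  uris <- ls(remote$store)
  paths <- vapply(uris, function(u) {
    e <- remote$store[[u]]
    resource_path(e$resource)
  }, character(1), USE.NAMES = FALSE)
  list_children(paths, prefix)
}

# shared listing semantics: immediate children of `prefix` among stored
# leaf paths, returned as slash-joined paths, sorted
list_children <- function(paths, prefix = "") {
  pre_parts <- if (nzchar(prefix)) strsplit(prefix, "/", fixed = TRUE)[[1]] else character(0)
  depth <- length(pre_parts)
  kids <- character(0)
  for (p in paths) {
    parts <- strsplit(p, "/", fixed = TRUE)[[1]]
    if (length(parts) <= depth) next
    if (depth > 0 && !identical(parts[seq_len(depth)], pre_parts)) next
    kids <- c(kids, paste(parts[seq_len(depth + 1L)], collapse = "/"))
  }
  sort(unique(kids), method = "radix")
}
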