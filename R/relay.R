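#' Chunk-addressed LRU cache tier
#'
#' Byte store keyed by chunk, with least-recently-used eviction under a byte
#' capacity.  Backs the caching relay; exposed directly so eviction behavior
#' is testable in isolation.  Any access — read hit or write — refreshes a
#' key's recency.  A single item larger than the whole capacity is refused
#' (pass-through mode: the relay serves it without caching).
#'
#' @param capacity_bytes Positive capacity in bytes.
#' @param dir Optional directory for an on-disk tier; `NULL` keeps bytes in
#'   memory.
#' @return An object of class `vk_cache`.
#' @export
lru_cache <- function(capacity_bytes, dir = NULL) {
  capacity_bytes <- as.numeric(capacity_bytes)
  if (!is.finite(capacity_bytes) || capacity_bytes <= 0)
    vk_stop("usage", "capacity_bytes must be positive")
  self <- new.env(parent = emptyenv())
  self$capacity <- capacity_bytes
  self$dir <- dir
  if (!is.null(dir)) dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  self$mem <- new.env(parent = emptyenv())
  self$sizes <- numeric(0)       # named by key
  self$order <- character(0)     # least-recent first, most-recent last
  self$hits <- 0L
  self$misses <- 0L
  class(self) <- "vk_cache"
  self
}

cache_file <- function(cache, key) {
  file.path(cache$dir, utils::URLencode(key, reserved = TRUE))
}

touch_key <- function(cache, key) {
  cache$order <- c(setdiff(cache$order, key), key)
}

#' @rdname lru_cache
#' @param cache A `vk_cache`.
#' @param key Chunk key string.
#' @return `cache_get()` returns the stored raw vector or `NULL` on miss
#'   (counting hit/miss either way).
#' @export
cache_get <- function(cache, key) {
  bytes <- if (is.null(cache$dir)) cache$mem[[key]] else {
    f <- cache_file(cache, key)
    if (key %in% names(cache$sizes) && file.exists(f))
      readBin(f, "raw", n = file.size(f)) else NULL
  }
  if (is.null(bytes)) {
    cache$misses <- cache$misses + 1L
    return(NULL)
  }
  cache$hits <- cache$hits + 1L
  touch_key(cache, key)
  bytes
}

#' @rdname lru_cache
#' @param bytes Raw vector to store.
#' @return `cache_put()` invisibly returns the keys evicted to make room (in
#'   eviction order); attribute `refused` is `TRUE` when the item alone
#'   exceeds capacity and was not cached.
#' @export
cache_put <- function(cache, key, bytes) {
  if (length(bytes) > cache$capacity)
    return(invisible(structure(character(0), refused = TRUE)))
  if (key %in% names(cache$sizes)) cache_drop(cache, key)
  if (is.null(cache$dir)) cache$mem[[key]] <- bytes
  else writeBin(bytes, cache_file(cache, key))
  cache$sizes[key] <- length(bytes)
  touch_key(cache, key)
  invisible(cache_evict(cache))
}

#' @rdname lru_cache
#' @return `cache_evict()` removes least-recently-used entries until stored
#'   bytes fit the capacity and returns the evicted keys in eviction order.
#' @export
cache_evict <- function(cache) {
  evicted <- character(0)
  while (sum(cache$sizes) > cache$capacity && length(cache$order)) {
    victim <- cache$order[1]
    cache_drop(cache, victim)
    evicted <- c(evicted, victim)
  }
  evicted
}

cache_drop <- function(cache, key) {
  if (is.null(cache$dir)) {
    if (!is.null(cache$mem[[key]])) rm(list = key, envir = cache$mem)
  } else {
    unlink(cache_file(cache, key))
  }
  cache$sizes <- cache$sizes[setdiff(names(cache$sizes), key)]
  cache$order <- setdiff(cache$order, key)
  invisible(key)
}

#' @rdname lru_cache
#' @export
cache_stats <- function(cache) {
  list(hits = cache$hits, misses = cache$misses,
       stored_bytes = unname(sum(cache$sizes)),
       capacity_bytes = cache$capacity,
       n_chunks = length(cache$sizes))
}

#' @rdname lru_cache
#' @param keys Keys to drop; `NULL` clears the whole tier.
#' @return `cache_invalidate()` returns the number of entries removed.
#' @export
cache_invalidate <- function(cache, keys = NULL) {
  if (is.null(keys)) keys <- names(cache$sizes)
  keys <- intersect(keys, names(cache$sizes))
  for (k in keys) cache_drop(cache, k)
  length(keys)
}

#' Daisy-chainable caching relay
#'
#' A relay answers cutout requests from a local chunk cache and fetches
#' misses from an upstream remote — which may itself be another relay, so
#' relays compose into a multi-tier cache.  Cache granularity equals the
#' upstream's chunk shape, so cache keys align with the server's cuboids and
#' a warm cache answers chunk-aligned traffic with zero upstream contact.
#' Writes are write-through: intersecting cached chunks are invalidated
#' before the write is forwarded upstream, so reads through the relay are
#' never stale (external writes that bypass the relay are out of contract).
#' The relay implements the remote trait, and [serve_relay()] exposes it over
#' the same REST dialect as [serve_reference()] plus `GET /v1/cache/stats`.
#'
#' @param upstream Any remote with the read capability.
#' @param capacity_bytes Cache capacity; must hold at least one chunk for
#'   caching to engage (smaller items pass through uncached).
#' @param cache_dir Optional directory for an on-disk cache tier.
#' @return A remote of class `vk_relay`.
#' @export
caching_relay <- function(upstream, capacity_bytes = 128 * 1024^2,
                          cache_dir = NULL) {
  self <- new.env(parent = emptyenv())
  self$upstream <- upstream
  self$tier <- lru_cache(capacity_bytes, cache_dir)
  self$meta_cache <- new.env(parent = emptyenv())
  self$upstream_fetches <- 0L
  class(self) <- c("vk_relay", "vk_remote")
  self
}

#' @export
remote_capabilities.vk_relay <- function(remote) {
  remote_capabilities(remote$upstream)
}

#' @export
get_metadata.vk_relay <- function(remote, resource) {
  path <- if (is.character(resource)) resource_path(parse_resource_uri(resource))
          else resource_path(resource)
  cached <- remote$meta_cache[[path]]
  if (!is.null(cached)) return(cached)
  meta <- get_metadata(remote$upstream, resource)
  remote$meta_cache[[path]] <- meta
  meta
}

#' @export
create_resource.vk_relay <- function(remote, resource, frame = resource$frame,
                                     chunks = default_chunk_shape()) {
  create_resource(remote$upstream, resource, frame, chunks)
}

#' @export
list_resources.vk_relay <- function(remote, prefix = "") {
  list_resources(remote$upstream, prefix)
}

#' @rdname caching_relay
#' @param remote The relay, as a remote-trait object.
#' @param request A `vk_request`.
#' @param workers Unused (chunks are served from cache or fetched serially so
#'   hit/miss accounting stays exact); accepted for trait compatibility.
#' @export
get_cutout.vk_relay <- function(remote, request, workers = 1L) {
  meta <- get_metadata(remote, request$resource)
  validate_request(request, meta$frame)
  ext <- extents_at(meta$frame, request$resolution)
  request$resource <- meta$resource
  plan <- decompose(request, meta$chunks)
  chunks <- attr(plan, "chunks")
  blocks <- vector("list", nrow(plan))
  for (r in seq_len(nrow(plan))) {
    key <- plan$key[r]
    bytes <- cache_get(remote$tier, key)
    if (!is.null(bytes)) {
      blocks[[r]] <- decode_volume(bytes, chunks, meta$dtype)
      next
    }
    box <- chunk_box(plan, r, ext)
    sub <- cutout_request(meta$resource,
                          c(box$start[1], box$stop[1]),
                          c(box$start[2], box$stop[2]),
                          c(box$start[3], box$stop[3]), request$resolution)
    clipped <- tryCatch({
      remote$upstream_fetches <- remote$upstream_fetches + 1L
      as.array(get_cutout(remote$upstream, sub))
    }, vk_upstream_unavailable_error = function(e) e,
       error = function(e) {
         if (inherits(e, "vk_error")) stop(e)
         e
       })
    if (inherits(clipped, "error"))
      vk_stop("upstream_unavailable",
              "chunk %s is not cached and upstream is unreachable: %s",
              key, conditionMessage(clipped))
    full <- new_volume_array(chunks, meta$dtype)
    sh <- box$stop - box$start
    full[seq_len(sh[1]), seq_len(sh[2]), seq_len(sh[3])] <- clipped
    cache_put(remote$tier, key, encode_voxels(full, meta$dtype))
    blocks[[r]] <- full
  }
  names(blocks) <- plan$key
  stitch(plan, blocks)
}

#' @rdname caching_relay
#' @param data Array to write (forwarded upstream after invalidation).
#' @export
post_cutout.vk_relay <- function(remote, request, data) {
  meta <- get_metadata(remote, request$resource)
  validate_request(request, meta$frame)
  invalidate(remote, request$resource, box = request,
             resolution = request$resolution)
  post_cutout(remote$upstream, request, data)
  invisible(remote)
}

#' Invalidate cached chunks
#'
#' Drops every cached chunk of `resource` that intersects `box` (a
#' `vk_request`, or `NULL` for all chunks of the resource; resource `NULL`
#' clears the whole cache).
#'
#' @param relay A `vk_relay`.
#' @param resource Resource (or URI) whose chunks to drop, or `NULL`.
#' @param box Optional `vk_request` restricting the invalidation.
#' @param resolution Resolution level of `box`.
#' @return Number of cache entries removed.
#' @export
invalidate <- function(relay, resource = NULL, box = NULL, resolution = 0L) {
  if (is.null(resource)) return(cache_invalidate(relay$tier))
  uri <- as_resource_uri(resource)
  all_keys <- names(relay$tier$sizes)
  mine <- all_keys[startsWith(all_keys, paste0(uri, "@"))]
  if (is.null(box)) return(cache_invalidate(relay$tier, mine))
  meta <- get_metadata(relay, resource)
  plan <- decompose(box, meta$chunks)
  cache_invalidate(relay$tier, intersect(mine, plan$key))
}

#' @rdname caching_relay
#' @param relay A `vk_relay`.
#' @export
relay_stats <- function(relay) {
  c(cache_stats(relay$tier), list(upstream_fetches = relay$upstream_fetches))
}

#' @rdname serve_reference
#' @param relay A [caching_relay()].
#' @export
serve_relay <- function(relay, host = "127.0.0.1", port = 8681,
                        writable = TRUE) {
  app <- reference_app(relay, writable = writable)
  httpuv::runServer(host, port, app)
}
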