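#' Chunk shapes
#'
#' Chunked stores subdivide volumes into fixed-shape cuboids.  Requests that
#' are aligned to those cuboid boundaries avoid downloading and cropping the
#' chunk periphery, which is why the decomposition below is the backbone of
#' every chunked remote and of the caching relay.  The default shape
#' `(512, 512, 16)` mirrors the cuboid used by common cloud stores and is
#' configurable per remote.
#'
#' @param cx,cy,cz Positive integers: voxels per chunk along X, Y, Z.
#' @return An object of class `vk_chunk_shape` (integer length-3 vector).
#' @export
chunk_shape <- function(cx = 512L, cy = 512L, cz = 16L) {
  v <- as.integer(c(cx, cy, cz))
  if (anyNA(v) || any(v < 1L))
    vk_stop("usage", "chunk shape components must be positive integers")
  structure(v, class = "vk_chunk_shape")
}

as_chunk_shape <- function(x) {
  if (inherits(x, "vk_chunk_shape")) return(x)
  if (length(x) == 3L) return(chunk_shape(x[1], x[2], x[3]))
  vk_stop("usage", "chunk shape must have three components")
}

#' Default chunk shape
#' @return The package default `chunk_shape(512, 512, 16)`.
#' @export
default_chunk_shape <- function() chunk_shape(512L, 512L, 16L)

chunk_key <- function(uri, resolution, i, j, k) {
  sprintf("%s@%d/%d_%d_%d", uri, resolution, i, j, k)
}

#' Decompose a cutout request into chunk-aligned blocks
#'
#' Splits the request box along the chunk grid.  Each plan entry names a chunk
#' (grid indices `i, j, k`), the intersection of that chunk with the request
#' in global voxel coordinates (`gx0:gx1` etc., half-open), and the same box
#' in request-local coordinates (`dx0:dx1` etc.).  The intersection boxes are
#' pairwise disjoint and tile the request exactly.  Plan order is
#' deterministic: k-major, then j, then i (i fastest).
#'
#' @param request A validated `vk_request`.
#' @param chunks A [chunk_shape()].
#' @return A data frame of class `vk_block_plan` with one row per touched
#'   chunk and a `key` column naming each chunk.
#' @examples
#' fr <- coordinate_frame(c(200, 200, 32))
#' ch <- channel_resource("c", "e", "ch", frame = fr)
#' req <- cutout_request(ch, c(10, 74), c(0, 64), c(0, 16))
#' decompose(req, chunk_shape(64, 64, 16))
#' @export
decompose <- function(request, chunks = default_chunk_shape()) {
  chunks <- as_chunk_shape(chunks)
  starts <- c(request$x[1], request$y[1], request$z[1])
  stops  <- c(request$x[2], request$y[2], request$z[2])
  lo <- starts %/% chunks
  hi <- (stops - 1L) %/% chunks
  grid <- expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3],
                      KEEP.OUT.ATTRS = FALSE)
  idx <- as.matrix(grid)                      # n x 3, i/j/k
  g0 <- pmax(sweep(idx, 2, as.integer(chunks), `*`),
             matrix(starts, nrow(idx), 3, byrow = TRUE))
  g1 <- pmin(sweep(idx + 1L, 2, as.integer(chunks), `*`),
             matrix(stops, nrow(idx), 3, byrow = TRUE))
  uri <- resource_uri(request$resource)
  plan <- data.frame(
    i = idx[, 1], j = idx[, 2], k = idx[, 3],
    gx0 = g0[, 1], gx1 = g1[, 1],
    gy0 = g0[, 2], gy1 = g1[, 2],
    gz0 = g0[, 3], gz1 = g1[, 3],
    dx0 = g0[, 1] - starts[1], dx1 = g1[, 1] - starts[1],
    dy0 = g0[, 2] - starts[2], dy1 = g1[, 2] - starts[2],
    dz0 = g0[, 3] - starts[3], dz1 = g1[, 3] - starts[3]
  )
  plan$key <- chunk_key(uri, request$resolution, plan$i, plan$j, plan$k)
  structure(plan, class = c("vk_block_plan", "data.frame"),
            request = request, chunks = chunks)
}

#' Number of chunks a request touches
#'
#' Closed form: `prod(floor((stop-1)/c) - floor(start/c) + 1)` over the three
#' axes; always equals `nrow(decompose(request, chunks))`.
#'
#' @inheritParams decompose
#' @return A positive integer (returned as double to avoid overflow for very
#'   large grids).
#' @export
chunks_touched <- function(request, chunks = default_chunk_shape()) {
  chunks <- as_chunk_shape(chunks)
  starts <- c(request$x[1], request$y[1], request$z[1])
  stops  <- c(request$x[2], request$y[2], request$z[2])
  prod(((stops - 1L) %/% chunks) - (starts %/% chunks) + 1)
}

#' Fraction of downloaded voxels that are chunk periphery
#'
#' Chunked stores return whole chunks; any part of a touched chunk outside the
#' request box is downloaded and cropped away.  This returns
#' `(touched_chunk_voxels - requested_voxels) / touched_chunk_voxels`.
#' Chunks clipped by the volume extents are counted at their clipped size:
#' nothing beyond the volume crosses the wire, so extent clipping contributes
#' no periphery and a request aligned to chunk boundaries *or* volume edges
#' scores exactly 0.
#'
#' @inheritParams decompose
#' @param frame Frame used to clip edge chunks; defaults to the resource's.
#' @return A real in `[0, 1)`.
#' @export
periphery_fraction <- function(request, chunks = default_chunk_shape(),
                               frame = request$resource$frame) {
  chunks <- as_chunk_shape(chunks)
  starts <- c(request$x[1], request$y[1], request$z[1])
  stops  <- c(request$x[2], request$y[2], request$z[2])
  ext <- if (!is.null(frame)) extents_at(frame, request$resolution) else NULL
  total <- 1
  for (a in 1:3) {
    lo <- starts[a] %/% chunks[a]
    hi <- (stops[a] - 1L) %/% chunks[a]
    cs <- (lo:hi) * chunks[a]
    ce <- pmin(cs + chunks[a], if (is.null(ext)) Inf else ext[a])
    total <- total * sum(ce - cs)
  }
  requested <- prod(stops - starts)
  (total - requested) / total
}

#' Stitch fetched chunk blocks into one dense volume
#'
#' Inverse of [decompose()]: given one full-chunk-shape array per plan entry
#' (zero-filled where a chunk extends past the stored data), assembles the
#' dense array of the request's shape.  Blocks are matched to plan entries by
#' name (the plan's `key` column), so arrival order is irrelevant.
#'
#' @param plan A `vk_block_plan` from [decompose()].
#' @param blocks Named list of 3D arrays, names matching `plan$key`, each of
#'   the plan's full chunk shape.
#' @return A `vk_block` holding the stitched volume.
#' @export
stitch <- function(plan, blocks) {
  request <- attr(plan, "request")
  chunks <- attr(plan, "chunks")
  dtype <- request$resource$dtype %||% "uint64"
  out <- new_volume_array(request_shape(request), dtype)
  if (is.null(names(blocks)) && length(blocks) == nrow(plan))
    names(blocks) <- plan$key
  for (r in seq_len(nrow(plan))) {
    key <- plan$key[r]
    blk <- blocks[[key]]
    if (is.null(blk))
      vk_stop("incomplete_plan", "missing chunk block '%s'", key)
    if (length(dim(blk)) != 3L || !all(dim(blk) == chunks))
      vk_stop("shape", "block '%s' has shape (%s), expected chunk shape (%s)",
              key, paste(dim(blk), collapse = "x"),
              paste(as.integer(chunks), collapse = "x"))
    sx <- (plan$gx0[r] - plan$i[r] * chunks[1] + 1L):(plan$gx1[r] - plan$i[r] * chunks[1])
    sy <- (plan$gy0[r] - plan$j[r] * chunks[2] + 1L):(plan$gy1[r] - plan$j[r] * chunks[2])
    sz <- (plan$gz0[r] - plan$k[r] * chunks[3] + 1L):(plan$gz1[r] - plan$k[r] * chunks[3])
    out[(plan$dx0[r] + 1L):plan$dx1[r],
        (plan$dy0[r] + 1L):plan$dy1[r],
        (plan$dz0[r] + 1L):plan$dz1[r]] <- blk[sx, sy, sz]
  }
  volume_block(out, request)
}

# Run one fetcher per plan entry, serially or with forked workers, and stitch.
# fetch_one(row) must return a full-chunk-shape array.  Results are identical
# for any worker count; workers > 1 uses parallel::mclapply.
fetch_and_stitch <- function(plan, fetch_one, workers = 1L) {
  rows <- seq_len(nrow(plan))
  arrays <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(rows, fetch_one, mc.cores = workers)
  } else {
    lapply(rows, fetch_one)
  }
  err <- vapply(arrays, inherits, logical(1), what = "try-error")
  if (any(err)) {
    cond <- attr(arrays[[which(err)[1]]], "condition")
    if (!is.null(cond)) stop(cond)
    vk_stop("runtime", "chunk fetch failed: %s", as.character(arrays[[which(err)[1]]]))
  }
  names(arrays) <- plan$key
  stitch(plan, arrays)
}

# full-chunk global voxel box of plan row r, clipped to `ext` (extents at the
# request resolution); used by fetchers that read whole chunks
chunk_box <- function(plan, r, ext) {
  chunks <- attr(plan, "chunks")
  c0 <- c(plan$i[r], plan$j[r], plan$k[r]) * chunks
  c1 <- pmin(c0 + chunks, ext)
  list(start = as.integer(c0), stop = as.integer(c1))
}
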