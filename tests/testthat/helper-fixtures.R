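# Shared fixtures and oracles for the suite.

test_frame <- function(extents = c(96L, 96L, 24L), ...) {
  coordinate_frame(extents, ...)
}

test_channel <- function(extents = c(96L, 96L, 24L), dtype = "uint8",
                         name = "ch", ...) {
  kind <- if (dtype == "uint64") "annotation" else "image"
  channel_resource("col", "exp", name, kind, dtype,
                   frame = test_frame(extents, ...))
}

# random half-open sub-box request of a resource, under the caller's RNG
random_request <- function(resource, frame = resource$frame) {
  ext <- extents_at(frame, 0L)
  s <- vapply(ext, function(e) {
    a <- sample.int(e, 1L) - 1L
    b <- a + sample.int(e - a, 1L)
    c(a, b)
  }, integer(2))
  cutout_request(resource, s[, 1], s[, 2], s[, 3])
}

random_chunk_shape <- function(max_side = 48L) {
  chunk_shape(sample.int(max_side, 1L), sample.int(max_side, 1L),
              sample.int(max_side, 1L))
}

# a remote of each writable kind, preloaded with the full ramp volume
ramp_loaded_remote <- function(kind = c("memory", "file"),
                               extents = c(96L, 96L, 24L),
                               chunks = chunk_shape(32L, 32L, 8L),
                               env = parent.frame()) {
  kind <- match.arg(kind)
  remote <- switch(kind,
                   memory = memory_remote(chunks = chunks),
                   file = file_chunk_remote(withr::local_tempdir(.local_envir = env),
                                            chunks = chunks))
  ch <- test_channel(extents)
  create_resource(remote, ch, chunks = chunks)
  full <- cutout_request(ch, c(0L, extents[1]), c(0L, extents[2]), c(0L, extents[3]))
  post_cutout(remote, full, ramp_formula(c(0L, extents[1]), c(0L, extents[2]),
                                         c(0L, extents[3])))
  list(remote = remote, resource = ch, extents = extents, chunks = chunks)
}

# Brute-force voxel enumeration oracles for the chunk geometry ------------

# chunk count by enumerating the chunk index of every voxel in the box
oracle_chunks_touched <- function(request, chunks) {
  xs <- request$x[1]:(request$x[2] - 1L)
  ys <- request$y[1]:(request$y[2] - 1L)
  zs <- request$z[1]:(request$z[2] - 1L)
  keys <- unique(as.vector(outer(outer(
    xs %/% chunks[1] * 1e12, ys %/% chunks[2] * 1e6, `+`),
    zs %/% chunks[3], `+`)))
  length(keys)
}

# periphery fraction by counting voxels in each touched (possibly
# extent-clipped) chunk one axis at a time
oracle_periphery <- function(request, chunks, ext) {
  total <- 1
  for (a in 1:3) {
    r <- request[[c("x", "y", "z")[a]]]
    idx <- (r[1]:(r[2] - 1L)) %/% chunks[a]
    sizes <- vapply(unique(idx), function(i) {
      min((i + 1L) * chunks[a], ext[a]) - i * chunks[a]
    }, numeric(1))
    total <- total * sum(sizes)
  }
  (total - prod(request_shape(request))) / total
}

# Brute-force per-cube table walk for the mesher --------------------------
# Walks every cube of the (padded) mask with nested loops and emits
# triangles straight from the case table, with naive vertex welding.  The
# vectorized extraction path must reproduce it exactly.
oracle_mesh <- function(mask) {
  d <- dim(mask)
  padded <- array(FALSE, d + 2L)
  padded[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  tbl <- voxelkit:::mc_case_table()
  corner <- voxelkit:::mc_corner_offsets()
  tris <- list()
  pd <- dim(padded)
  for (x in 1:(pd[1] - 1L)) for (y in 1:(pd[2] - 1L)) for (z in 1:(pd[3] - 1L)) {
    case <- 0
    for (c in 0:7) {
      o <- corner[c + 1L, ]
      if (padded[x + o[1], y + o[2], z + o[3]]) case <- case + 2^c
    }
    if (case == 0 || case == 255) next
    offs <- tbl[[case + 1L]]
    if (!nrow(offs)) next
    org <- c(x, y, z) - 2L         # 0-based, minus the pad
    for (t in seq_len(nrow(offs) / 3L)) {
      tris[[length(tris) + 1L]] <-
        sweep(offs[(3L * t - 2L):(3L * t), , drop = FALSE], 2,
              as.numeric(org), `+`)
    }
  }
  # weld: canonical vertex table in order of first appearance
  verts <- matrix(numeric(0), 0, 3)
  keys <- character(0)
  index <- function(p) {
    k <- paste(round(p * 4), collapse = ",")
    i <- match(k, keys)
    if (is.na(i)) {
      verts <<- rbind(verts, p)
      keys <<- c(keys, k)
      i <- length(keys)
    }
    i
  }
  tmat <- t(vapply(tris, function(tr) c(index(tr[1, ]), index(tr[2, ]),
                                        index(tr[3, ])), numeric(3)))
  list(vertices = unname(verts), triangles = tmat)
}

# canonical form for comparing triangle soups regardless of vertex order:
# sorted rows of sorted per-triangle vertex coordinate triples
canonical_triangles <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  if (!nrow(tr)) return(matrix(numeric(0), 0, 9))
  soup <- t(vapply(seq_len(nrow(tr)), function(i) {
    pts <- v[tr[i, ], , drop = FALSE]
    pts <- pts[order(pts[, 1], pts[, 2], pts[, 3]), , drop = FALSE]
    as.vector(t(pts))
  }, numeric(9)))
  soup[do.call(order, as.data.frame(soup)), , drop = FALSE]
}
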