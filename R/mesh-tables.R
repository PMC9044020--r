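# Marching-cubes case table.
#
# The 256-entry per-cube lookup table is *generated*, not transcribed: the
# unit cube is split into the six Kuhn tetrahedra around the main diagonal
# (corner 0 -> corner 7), each tetrahedron is contoured by the four-bit
# marching-tetrahedra case analysis, and the resulting triangles are
# concatenated per cube corner configuration.  The Kuhn subdivision is
# translation-consistent — the face diagonals of adjacent cubes coincide — so
# the surface is watertight and consistently oriented by construction, and
# there are no ambiguous cases to resolve.  On a binary mask contoured at
# iso-level 0.5, linear interpolation places every vertex at the midpoint of
# a tetrahedron edge, so each table entry is a fixed set of vertex offsets
# (multiples of 1/4) within the unit cube.
#
# Corner numbering: corner c sits at (bit0(c), bit1(c), bit2(c)) in (x,y,z).

.vk_mesh_env <- new.env(parent = emptyenv())

mc_corner_offsets <- function() {
  t(vapply(0:7, function(c) {
    c(bitwAnd(c, 1L), bitwAnd(bitwShiftR(c, 1L), 1L), bitwAnd(bitwShiftR(c, 2L), 1L))
  }, integer(3)))
}

# the six monotone 0 -> 7 lattice paths; each is one Kuhn tetrahedron
mc_kuhn_tets <- function() {
  list(c(0L, 1L, 3L, 7L), c(0L, 1L, 5L, 7L), c(0L, 2L, 3L, 7L),
       c(0L, 2L, 6L, 7L), c(0L, 4L, 5L, 7L), c(0L, 4L, 6L, 7L))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# triangles (rows of vertex offsets, 3 rows per triangle) for one tetrahedron
# given the per-corner inside flags; oriented with normals pointing from the
# inside corners toward the outside corners
tet_triangles <- function(tet, inside) {
  pos <- mc_corner_offsets()[tet + 1L, , drop = FALSE]
  ins <- inside[tet + 1L]
  n_in <- sum(ins)
  if (n_in == 0L || n_in == 4L) return(NULL)
  mid <- function(a, b) (pos[a, ] + pos[b, ]) / 2
  orient <- function(tri, dir_out) {
    n <- cross3(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
    d <- sum(n * dir_out)
    stopifnot(abs(d) > 1e-12)          # build-time sanity: never ambiguous
    if (d < 0) tri[c(1, 3, 2), , drop = FALSE] else tri
  }
  if (n_in == 1L) {
    a <- which(ins); o <- which(!ins)
    tri <- rbind(mid(a, o[1]), mid(a, o[2]), mid(a, o[3]))
    return(orient(tri, colMeans(pos[o, , drop = FALSE]) - pos[a, ]))
  }
  if (n_in == 3L) {
    o <- which(!ins); a <- which(ins)
    tri <- rbind(mid(o, a[1]), mid(o, a[2]), mid(o, a[3]))
    return(orient(tri, pos[o, ] - colMeans(pos[a, , drop = FALSE])))
  }
  # two in, two out: the separating quad, split along one diagonal
  a <- which(ins); b <- which(!ins)
  q <- rbind(mid(a[1], b[1]), mid(a[1], b[2]), mid(a[2], b[2]), mid(a[2], b[1]))
  dir <- colMeans(pos[b, , drop = FALSE]) - colMeans(pos[a, , drop = FALSE])
  rbind(orient(q[c(1, 2, 3), , drop = FALSE], dir),
        orient(q[c(1, 3, 4), , drop = FALSE], dir))
}

# list of 256 matrices; entry [case + 1] has 3 rows per triangle, columns
# x/y/z vertex offsets within the unit cube
mc_case_table <- function() {
  tbl <- .vk_mesh_env$table
  if (!is.null(tbl)) return(tbl)
  tets <- mc_kuhn_tets()
  tbl <- vector("list", 256L)
  for (case in 0:255) {
    inside <- bitwAnd(bitwShiftR(case, 0:7), 1L) == 1L
    rows <- lapply(tets, tet_triangles, inside = inside)
    rows <- rows[!vapply(rows, is.null, logical(1))]
    tbl[[case + 1L]] <- if (length(rows)) do.call(rbind, rows)
                        else matrix(numeric(0), 0L, 3L)
  }
  .vk_mesh_env$table <- tbl
  tbl
}
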