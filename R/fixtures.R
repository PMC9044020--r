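#' Synthetic test volumes
#'
#' Seeded generators for labeled balls, tubes, deterministic ramps and
#' Voronoi label fields.  They stand in for external connectomics datasets so
#' that every operation in the package — cutouts, meshing, caching, transfer
#' — is exercisable offline, and they double as analytic oracles: the ramp
#' volume is recomputable voxel-by-voxel from its formula, and ball voxel
#' counts converge to the closed-form sphere volume.
#'
#' Voxel `(ix, iy, iz)` (0-based) occupies the unit cube
#' `[ix, ix+1) x ...`; its *center* sits at `(ix+0.5, iy+0.5, iz+0.5)`.
#' Inside/outside tests use voxel centers, which keeps ball voxel counts
#' unbiased around the analytic volume.
#'
#' @name fixtures
NULL

fixture_resource <- function(shape, dtype, voxel_size = c(1, 1, 1),
                             channel_kind = NULL, name = "fixture") {
  if (is.null(channel_kind))
    channel_kind <- if (dtype == "uint64") "annotation" else "image"
  frame <- coordinate_frame(shape, voxel_size)
  data_instance_resource(name, channel_kind, dtype, frame)
}

fixture_block <- function(arr, shape, dtype, voxel_size, name) {
  res <- fixture_resource(shape, dtype, voxel_size, name = name)
  req <- cutout_request(res, c(0L, shape[1]), c(0L, shape[2]), c(0L, shape[3]))
  volume_block(arr, req)
}

# squared distance from every voxel center to `center`, as an (X,Y,Z) array
center_dist2 <- function(shape, center) {
  dx <- (seq_len(shape[1]) - 0.5 - center[1])^2
  dy <- (seq_len(shape[2]) - 0.5 - center[2])^2
  dz <- (seq_len(shape[3]) - 0.5 - center[3])^2
  outer(outer(dx, dy, `+`), dz, `+`)
}

#' @rdname fixtures
#' @param shape Integer vector `c(X, Y, Z)`.
#' @param center Ball center in continuous voxel coordinates (defaults to the
#'   volume center).
#' @param radius Ball radius in voxels.
#' @param label Nonzero foreground label.
#' @param voxel_size Physical voxel size recorded in the block's frame.
#' @param dtype Voxel dtype (`uint64` by default: fixtures are segmentation).
#' @return A `vk_block`.
#' @examples
#' ball <- make_ball_volume(c(25, 25, 25), radius = 10)
#' sum(as.array(ball) != 0) / (4 / 3 * pi * 10^3)  # close to 1
#' @export
make_ball_volume <- function(shape, center = shape / 2, radius, label = 1,
                             voxel_size = c(1, 1, 1), dtype = "uint64") {
  shape <- as.integer(shape)
  if (any(center - radius < 1) || any(center + radius > shape - 1))
    vk_stop("bounds",
            "ball (center %s, radius %g) must fit inside the volume with a one-voxel margin",
            paste(format(center), collapse = ","), radius)
  arr <- new_volume_array(shape, dtype)
  arr[center_dist2(shape, center) <= radius^2] <- label
  fixture_block(arr, shape, dtype, voxel_size, "ball")
}

#' @rdname fixtures
#' @param axis Tube axis, one of `"x"`, `"y"`, `"z"`.
#' @param span Half-open `c(start, stop)` extent of the tube along its axis;
#'   default spans the full volume.
#' @export
make_tube_volume <- function(shape, axis = "z", center = NULL, radius,
                             span = NULL, label = 1,
                             voxel_size = c(1, 1, 1), dtype = "uint64") {
  shape <- as.integer(shape)
  ax <- match(axis, c("x", "y", "z"))
  if (is.na(ax)) vk_stop("usage", "axis must be 'x', 'y' or 'z'")
  cross <- setdiff(1:3, ax)
  if (is.null(center)) center <- shape[cross] / 2
  if (is.null(span)) span <- c(0L, shape[ax])
  d1 <- (seq_len(shape[cross[1]]) - 0.5 - center[1])^2
  d2 <- (seq_len(shape[cross[2]]) - 0.5 - center[2])^2
  disk <- outer(d1, d2, `+`) <= radius^2
  along <- seq_len(shape[ax]) - 1L
  inside_ax <- along >= span[1] & along < span[2]
  arr <- new_volume_array(shape, dtype)
  mask <- array(FALSE, shape)
  perm <- order(c(cross, ax))
  mask_c <- outer(disk, inside_ax, `&`)      # (cross1, cross2, axis)
  mask <- aperm(mask_c, perm)
  arr[mask] <- label
  fixture_block(arr, shape, dtype, voxel_size, "tube")
}

#' @rdname fixtures
#' @param modulus Values are `(x + 10 y + 100 z) mod modulus`; must fit the
#'   dtype.  The default 251 (largest prime below 256) fits `uint8`.
#' @examples
#' ramp <- make_ramp_volume(c(8, 8, 8))
#' as.array(ramp)[4, 3, 2]  # (x=3) + 10*(y=2) + 100*(z=1) mod 251
#' @export
make_ramp_volume <- function(shape, modulus = 251L, dtype = "uint8",
                             voxel_size = c(1, 1, 1)) {
  shape <- as.integer(shape)
  if (modulus - 1 > dtype_info(dtype)$max)
    vk_stop("dtype", "modulus %d does not fit %s", modulus, dtype)
  x <- seq_len(shape[1]) - 1L
  y <- seq_len(shape[2]) - 1L
  z <- seq_len(shape[3]) - 1L
  arr <- outer(outer(x, 10L * y, `+`), 100L * z, `+`) %% as.integer(modulus)
  fixture_block(arr, shape, dtype, voxel_size, "ramp")
}

#' Ramp-volume oracle
#'
#' Evaluates the ramp formula directly over a half-open box — the independent
#' reference every chunked read path is checked against.
#'
#' @param x,y,z Half-open ranges `c(start, stop)` in global voxel
#'   coordinates.
#' @param modulus Ramp modulus.
#' @return Integer array of shape `(diff(x), diff(y), diff(z))`.
#' @export
ramp_formula <- function(x, y, z, modulus = 251L) {
  xs <- x[1]:(x[2] - 1L)
  ys <- y[1]:(y[2] - 1L)
  zs <- z[1]:(z[2] - 1L)
  outer(outer(xs, 10L * ys, `+`), 100L * zs, `+`) %% as.integer(modulus)
}

#' @rdname fixtures
#' @param n_labels Number of Voronoi sites/labels (>= 1).
#' @param seed Integer seed; identical seed and arguments give bit-identical
#'   volumes, and the caller's RNG state is untouched.
#' @examples
#' lab <- make_random_labels(c(16, 16, 16), n_labels = 4, seed = 7)
#' sort(unique(as.vector(as.array(lab))))
#' @export
make_random_labels <- function(shape, n_labels, seed,
                               voxel_size = c(1, 1, 1), dtype = "uint64") {
  shape <- as.integer(shape)
  n_labels <- as.integer(n_labels)
  if (n_labels < 1L) vk_stop("usage", "n_labels must be >= 1")
  if (n_labels > prod(shape)) vk_stop("usage", "more labels than voxels")
  local_rng(seed)
  sites_lin <- sample.int(prod(shape), n_labels)   # distinct voxel sites
  idx <- arrayInd(sites_lin, shape) - 0.5          # site = its voxel's center
  best_d <- array(Inf, shape)
  best_l <- new_volume_array(shape, dtype)
  for (l in seq_len(n_labels)) {
    d <- center_dist2(shape, idx[l, ])
    take <- d < best_d                             # ties keep the lower label
    best_d[take] <- d[take]
    best_l[take] <- l
  }
  fixture_block(best_l, shape, dtype, voxel_size, "labels")
}
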