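test_that("absent labels and empty volumes give empty meshes, not errors", {
  z <- array(0, c(8, 8, 8))
  m <- marching_cubes(z, 1)
  expect_equal(nrow(m$vertices), 0L)
  expect_equal(nrow(m$triangles), 0L)
  ball <- make_ball_volume(c(15L, 15L, 15L), radius = 4)
  m2 <- marching_cubes(ball, 99)
  expect_equal(nrow(m2$vertices), 0L)
  expect_error(marching_cubes(array(0, c(4, 4)), 1), class = "vk_shape_error")
})

test_that("the vectorized extractor reproduces the brute-force per-cube table walk", {
  shapes <- list(
    single = { a <- array(0, c(5, 5, 5)); a[3, 3, 3] <- 1; a },
    pair   = { a <- array(0, c(6, 5, 5)); a[3:4, 3, 3] <- 1; a },
    blob   = as.array(make_ball_volume(c(11L, 11L, 11L), radius = 3)),
    tube   = as.array(make_tube_volume(c(9L, 9L, 12L), radius = 2.5,
                                       span = c(2L, 10L))))
  for (nm in names(shapes)) {
    arr <- shapes[[nm]]
    fast <- marching_cubes(arr, 1)
    slow <- oracle_mesh(arr == 1)
    expect_equal(nrow(fast$vertices), nrow(slow$vertices), info = nm)
    expect_equal(nrow(fast$triangles), nrow(slow$triangles), info = nm)
    expect_equal(canonical_triangles(fast), canonical_triangles(slow),
                 tolerance = 1e-12, info = nm)
  }
})

test_that("a single foreground voxel meshes to the known closed polyhedron", {
  a <- array(0, c(5, 5, 5)); a[3, 3, 3] <- 1
  st <- mesh_stats(marching_cubes(a, 1))
  # counts recorded from the brute-force per-cube table walk (oracle_mesh)
  expect_equal(st$n_vertices, 14L)
  expect_equal(st$n_triangles, 24L)
  expect_true(st$watertight)
  expect_equal(st$euler_characteristic, 2L)
  expect_equal(st$enclosed_volume, 0.5)
})

test_that("ball meshes are watertight genus-0 surfaces with converging volume", {
  errs <- numeric(0)
  for (r in c(5, 10, 20)) {
    s <- as.integer(2 * r + 5)
    ball <- make_ball_volume(c(s, s, s), radius = r)
    st <- mesh_stats(marching_cubes(ball, 1))
    true_vol <- 4 / 3 * pi * r^3
    rel <- abs(st$enclosed_volume - true_vol) / true_vol
    expect_true(st$watertight, info = paste("r =", r))
    expect_equal(st$euler_characteristic, 2L, info = paste("r =", r))
    expect_lt(rel, 0.05)
    errs <- c(errs, rel)
  }
  expect_true(all(diff(errs) < 0))   # error shrinks with radius
})

test_that("meshing is translation-equivariant", {
  base <- array(0, c(24, 24, 24))
  ball <- as.array(make_ball_volume(c(13L, 13L, 13L), radius = 4))
  base[2:14, 2:14, 2:14] <- ball
  shifted <- array(0, c(24, 24, 24))
  shifted[9:21, 7:19, 5:17] <- ball            # translate by (7, 5, 3)
  m0 <- marching_cubes(base, 1)
  m1 <- marching_cubes(shifted, 1)
  t0 <- canonical_triangles(m0)
  t1 <- canonical_triangles(m1)
  shift <- rep(c(7, 5, 3), 3)
  expect_equal(t1, t0 + matrix(shift, nrow(t0), 9, byrow = TRUE),
               tolerance = 1e-4)
})

test_that("voxel size scales vertices linearly and volume cubically", {
  ball <- make_ball_volume(c(17L, 17L, 17L), radius = 6)
  m1 <- marching_cubes(ball, 1, voxel_size = c(1, 1, 1))
  m2 <- marching_cubes(ball, 1, voxel_size = c(2, 2, 2))
  expect_equal(m2$vertices, m1$vertices * 2, tolerance = 1e-12)
  expect_equal(mesh_stats(m2)$enclosed_volume,
               8 * mesh_stats(m1)$enclosed_volume, tolerance = 1e-9)
  # anisotropic voxels scale each axis independently
  ma <- marching_cubes(ball, 1, voxel_size = c(4, 4, 40))
  expect_equal(ma$vertices[, 3] / m1$vertices[, 3],
               rep(40, nrow(m1$vertices)))
})

test_that("a label's mesh is unchanged by other labels with disjoint support", {
  a <- array(0, c(30, 16, 16))
  ballA <- as.array(make_ball_volume(c(13L, 13L, 13L), radius = 4))
  a[2:14, 2:14, 2:14] <- ballA
  b <- a
  b[20:26, 5:11, 5:11] <- 7    # second object, label 7
  mA_alone <- marching_cubes(a, 1)
  mA_with <- marching_cubes(b, 1)
  expect_equal(mA_alone$vertices, mA_with$vertices)
  expect_equal(mA_alone$triangles, mA_with$triangles)
  m7 <- marching_cubes(b, 7)
  expect_true(mesh_stats(m7)$watertight)
  expect_equal(mesh_stats(m7)$enclosed_volume, 7 * 7 * 7, tolerance = 0.3)
})

test_that("vertices stay inside the source box expanded by one voxel, in physical units", {
  loaded <- ramp_loaded_remote("memory")
  seg <- test_channel(c(40L, 40L, 20L), dtype = "uint64", name = "seg")
  rem <- memory_remote()
  create_resource(rem, seg)
  ball <- as.array(make_ball_volume(c(21L, 21L, 15L), radius = 5))
  post_cutout(rem, cutout_request(seg, c(10, 31), c(12, 33), c(3, 18)), ball)
  box <- cutout_request(seg, c(8, 34), c(10, 36), c(1, 19))
  m <- mesh_for_id(rem, seg, 1, box)
  vs <- voxel_size_at(seg$frame, 0L)
  lo <- (c(8, 10, 1) - 1) * vs
  hi <- (c(34, 36, 19) + 1) * vs
  expect_true(all(sweep(m$vertices, 2, lo, `>=`)))
  expect_true(all(sweep(m$vertices, 2, hi, `<=`)))
  expect_true(mesh_stats(m)$watertight)
})

test_that("meshes are identical across remotes holding the same voxels", {
  seg <- test_channel(c(40L, 40L, 20L), dtype = "uint64", name = "seg")
  mem <- memory_remote()
  fx <- file_chunk_remote(withr::local_tempdir(), chunks = chunk_shape(16, 16, 8))
  ball <- as.array(make_ball_volume(c(21L, 21L, 15L), radius = 6))
  for (rem in list(mem, fx)) {
    create_resource(rem, seg)
    post_cutout(rem, cutout_request(seg, c(10, 31), c(10, 31), c(2, 17)), ball)
  }
  box <- cutout_request(seg, c(0, 40), c(0, 40), c(0, 20))
  m_mem <- mesh_for_id(mem, seg, 1, box)
  m_fx <- mesh_for_id(fx, seg, 1, box)
  expect_equal(m_mem$vertices, m_fx$vertices)
  expect_equal(m_mem$triangles, m_fx$triangles)
})

test_that("boxes clipping an object yield open meshes when padding is off", {
  ball <- as.array(make_ball_volume(c(21L, 21L, 21L), radius = 7))
  half <- ball[1:10, , ]      # clip through the middle
  m_open <- marching_cubes(half, 1, pad = FALSE)
  st <- mesh_stats(m_open)
  expect_false(st$watertight)
  # with padding the clip face is capped and the surface closes
  m_closed <- marching_cubes(half, 1, pad = TRUE)
  expect_true(mesh_stats(m_closed)$watertight)
})

test_that("mesh_stats matches closed forms on a hand-built cube surface", {
  # unit cube as 12 triangles over 8 vertices
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  idx <- function(x, y, z) x + 2 * y + 4 * z + 1
  quads <- list(
    c(idx(0,0,0), idx(0,1,0), idx(1,1,0), idx(1,0,0)),   # z=0, normal -z
    c(idx(0,0,1), idx(1,0,1), idx(1,1,1), idx(0,1,1)),   # z=1, normal +z
    c(idx(0,0,0), idx(1,0,0), idx(1,0,1), idx(0,0,1)),   # y=0
    c(idx(0,1,0), idx(0,1,1), idx(1,1,1), idx(1,1,0)),   # y=1
    c(idx(0,0,0), idx(0,0,1), idx(0,1,1), idx(0,1,0)),   # x=0
    c(idx(1,0,0), idx(1,1,0), idx(1,1,1), idx(1,0,1)))   # x=1
  tris <- do.call(rbind, lapply(quads, function(q)
    rbind(q[c(1, 2, 3)], q[c(1, 3, 4)])))
  cube <- voxelkit:::new_mesh(v, tris, 1, NULL)
  st <- mesh_stats(cube)
  expect_equal(st$n_vertices, 8L)
  expect_equal(st$n_triangles, 12L)
  expect_equal(st$n_edges, 18L)
  expect_equal(st$euler_characteristic, 2L)
  expect_true(st$watertight)
  expect_equal(st$enclosed_volume, 1.0)
  # removing one face breaks watertightness
  broken <- voxelkit:::new_mesh(v, tris[-1, , drop = FALSE], 1, NULL)
  expect_false(mesh_stats(broken)$watertight)
})

test_that("mesh dispatch honors server-side capability and rejects unreadable remotes", {
  expect_error(remote_mesh(memory_remote(), NULL, 1, NULL),
               class = "vk_capability_error")
  # a remote advertising mesh_server_side gets delegated to
  fake <- structure(new.env(), class = c("vk_fake_mesher", "vk_remote"))
  assign("remote_capabilities.vk_fake_mesher",
         function(remote) c("read", "mesh_server_side"), envir = globalenv())
  assign("remote_mesh.vk_fake_mesher",
         function(remote, resource, label, box) "delegated", envir = globalenv())
  withr::defer({
    rm("remote_capabilities.vk_fake_mesher", "remote_mesh.vk_fake_mesher",
       envir = globalenv())
  })
  registerS3method("remote_capabilities", "vk_fake_mesher",
                   get("remote_capabilities.vk_fake_mesher", globalenv()))
  registerS3method("remote_mesh", "vk_fake_mesher",
                   get("remote_mesh.vk_fake_mesher", globalenv()))
  expect_identical(mesh_for_id(fake, "instance://x", 1, NULL), "delegated")
})
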