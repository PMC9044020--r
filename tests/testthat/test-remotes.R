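remote_kinds <- c("memory", "file")

make_remote <- function(kind, chunks = chunk_shape(32, 32, 8),
                        env = parent.frame()) {
  switch(kind,
         memory = memory_remote(chunks = chunks),
         file = file_chunk_remote(withr::local_tempdir(.local_envir = env),
                                  chunks = chunks))
}

for (kind in remote_kinds) {
  test_that(sprintf("%s remote: fresh resources read as zeros and duplicates are rejected", kind), {
    rem <- make_remote(kind)
    ch <- test_channel(c(128L, 128L, 32L))
    create_resource(rem, ch)
    blk <- get_cutout(rem, cutout_request(ch, c(0, 8), c(0, 8), c(0, 8)))
    expect_true(all(as.array(blk) == 0))
    expect_error(create_resource(rem, ch), class = "vk_already_exists_error")
    expect_error(get_cutout(rem, cutout_request(test_channel(c(8L, 8L, 8L), name = "ghost"),
                                                c(0, 8), c(0, 8), c(0, 8))),
                 class = "vk_not_found_error")
  })

  test_that(sprintf("%s remote: ramp writes read back exactly, everywhere", kind), {
    loaded <- ramp_loaded_remote(kind)
    full <- get_cutout(loaded$remote,
                       cutout_request(loaded$resource, c(0, 96), c(0, 96), c(0, 24)))
    expect_identical(full$data, ramp_formula(c(0, 96), c(0, 96), c(0, 24)))
    local_rng(19)
    for (i in 1:25) {
      req <- random_request(loaded$resource)
      blk <- get_cutout(loaded$remote, req)
      expect_identical(blk$data,
                       ramp_formula(req$x, req$y, req$z))
    }
  })

  test_that(sprintf("%s remote: overlapping writes are last-writer-wins", kind), {
    rem <- make_remote(kind)
    ch <- test_channel(c(64L, 64L, 16L))
    create_resource(rem, ch)
    post_cutout(rem, cutout_request(ch, c(0, 32), c(0, 32), c(0, 8)),
                array(1L, c(32, 32, 8)))
    post_cutout(rem, cutout_request(ch, c(16, 48), c(16, 48), c(4, 12)),
                array(2L, c(32, 32, 8)))
    u <- as.array(get_cutout(rem, cutout_request(ch, c(0, 48), c(0, 48), c(0, 12))))
    expect_equal(u[20, 20, 6], 2L)   # overlap: B wins
    expect_equal(u[5, 5, 2], 1L)     # A-only region intact
    expect_equal(u[45, 45, 12], 2L)
    expect_equal(u[40, 5, 2], 0L)    # untouched region stays zero
  })

  test_that(sprintf("%s remote: dtype and shape mismatches are rejected, never cast", kind), {
    rem <- make_remote(kind)
    seg <- test_channel(c(32L, 32L, 8L), dtype = "uint64", name = "seg")
    create_resource(rem, seg)
    req <- cutout_request(seg, c(0, 8), c(0, 8), c(0, 8))
    expect_error(post_cutout(rem, req, with_dtype(array(1L, c(8, 8, 8)), "uint16")),
                 class = "vk_dtype_error")
    expect_error(post_cutout(rem, req, array(1L, c(8, 8, 4))),
                 class = "vk_shape_error")
    img <- test_channel(c(32L, 32L, 8L), dtype = "uint8", name = "img")
    create_resource(rem, img)
    reqi <- cutout_request(img, c(0, 8), c(0, 8), c(0, 8))
    expect_error(post_cutout(rem, reqi, array(300L, c(8, 8, 8))),
                 class = "vk_dtype_error")   # out of uint8 range
    expect_error(post_cutout(rem, reqi, with_dtype(array(1, c(8, 8, 8)), "uint64")),
                 class = "vk_dtype_error")
  })

  test_that(sprintf("%s remote: listing returns sorted children per level", kind), {
    rem <- make_remote(kind)
    fr <- test_frame(c(16L, 16L, 8L))
    create_resource(rem, channel_resource("a", "b", "d", frame = fr))
    create_resource(rem, channel_resource("a", "b", "c", frame = fr))
    create_resource(rem, channel_resource("a", "z", "w", frame = fr))
    create_resource(rem, data_instance_resource("vol", frame = fr))
    expect_identical(list_resources(rem, "a/b"), c("a/b/c", "a/b/d"))
    expect_identical(list_resources(rem, "a"), c("a/b", "a/z"))
    expect_identical(list_resources(rem), c("a", "vol"))
    expect_identical(list_resources(rem, "nope"), character(0))
  })
}

test_that("parallel and serial chunked reads are bit-identical", {
  loaded <- ramp_loaded_remote("file")
  local_rng(23)
  for (i in 1:30) {
    req <- random_request(loaded$resource)
    s1 <- get_cutout(loaded$remote, req, workers = 1L)
    s4 <- get_cutout(loaded$remote, req, workers = 4L)
    expect_identical(s1$data, s4$data)
  }
})

test_that("file remotes survive close and reopen (durability)", {
  root <- withr::local_tempdir()
  fx <- file_chunk_remote(root, chunks = chunk_shape(16, 16, 8))
  ch <- test_channel(c(48L, 48L, 16L))
  create_resource(fx, ch)
  post_cutout(fx, cutout_request(ch, c(0, 48), c(0, 48), c(0, 16)),
              ramp_formula(c(0, 48), c(0, 48), c(0, 16)))
  rm(fx)
  fx2 <- file_chunk_remote(root)
  blk <- get_cutout(fx2, cutout_request(ch, c(3, 40), c(7, 44), c(2, 14)))
  expect_identical(blk$data, ramp_formula(c(3, 40), c(7, 44), c(2, 14)))
  meta <- get_metadata(fx2, ch)
  expect_identical(as.integer(meta$chunks), c(16L, 16L, 8L))
  expect_identical(meta$frame$extents, c(48L, 48L, 16L))
})

test_that("file metadata documents round-trip read -> write -> read", {
  root <- withr::local_tempdir()
  fx <- file_chunk_remote(root)
  fr <- coordinate_frame(c(100L, 90L, 17L), voxel_size = c(4, 4, 40),
                         num_resolutions = 3L)
  ch <- channel_resource("c", "e", "seg", "annotation", frame = fr)
  create_resource(fx, ch, chunks = chunk_shape(20, 20, 5))
  m1 <- get_metadata(fx, ch)
  path <- file.path(root, "c", "e", "seg", "meta.json")
  txt1 <- readLines(path)
  writeLines(txt1, path)                      # rewrite verbatim
  m2 <- get_metadata(file_chunk_remote(root), ch)
  expect_identical(voxelkit:::frame_to_list(m1$frame), voxelkit:::frame_to_list(m2$frame))
  expect_identical(m1$dtype, m2$dtype)
  expect_identical(as.integer(m1$chunks), as.integer(m2$chunks))
})

test_that("writing a single voxel creates exactly one chunk file", {
  root <- withr::local_tempdir()
  fx <- file_chunk_remote(root, chunks = chunk_shape(16, 16, 8))
  ch <- test_channel(c(64L, 64L, 16L))
  create_resource(fx, ch)
  one <- array(0L, c(1, 1, 1)); one[1] <- 5L
  post_cutout(fx, cutout_request(ch, c(33, 34), c(33, 34), c(9, 10)), one)
  files <- list.files(root, pattern = "\\.bin$", recursive = TRUE)
  expect_length(files, 1L)
  # and an all-zero overwrite removes it again (absent file <=> zero chunk)
  post_cutout(fx, cutout_request(ch, c(33, 34), c(33, 34), c(9, 10)),
              array(0L, c(1, 1, 1)))
  expect_length(list.files(root, pattern = "\\.bin$", recursive = TRUE), 0L)
})

test_that("edge chunks are stored truncated but read back zero-padded", {
  root <- withr::local_tempdir()
  fx <- file_chunk_remote(root, chunks = chunk_shape(32, 32, 8))
  ch <- test_channel(c(40L, 40L, 10L))   # not a chunk multiple
  create_resource(fx, ch)
  post_cutout(fx, cutout_request(ch, c(0, 40), c(0, 40), c(0, 10)),
              ramp_formula(c(0, 40), c(0, 40), c(0, 10)))
  edge <- file.path(root, "col", "exp", "ch", "res0", "1_1_1.bin")
  expect_true(file.exists(edge))
  expect_equal(file.size(edge), 8 * 8 * 2)   # (40-32)^2 * (10-8), uint8
  blk <- get_cutout(fx, cutout_request(ch, c(30, 40), c(30, 40), c(6, 10)))
  expect_identical(blk$data, ramp_formula(c(30, 40), c(30, 40), c(6, 10)))
})

test_that("uint64 annotation volumes round-trip through chunked files", {
  root <- withr::local_tempdir()
  fx <- file_chunk_remote(root, chunks = chunk_shape(8, 8, 4))
  seg <- test_channel(c(16L, 16L, 8L), dtype = "uint64", name = "seg")
  create_resource(fx, seg)
  vals <- array(0, c(16, 16, 8))
  vals[1, 1, 1] <- 2^40 + 123
  vals[16, 16, 8] <- 987654321987
  post_cutout(fx, cutout_request(seg, c(0, 16), c(0, 16), c(0, 8)), vals)
  back <- as.array(get_cutout(fx, cutout_request(seg, c(0, 16), c(0, 16), c(0, 8))))
  expect_identical(back, vals)
})

test_that("in-memory and chunked-file remotes are interchangeable under a random script", {
  mem <- memory_remote(chunks = chunk_shape(32, 32, 8))
  fx <- file_chunk_remote(withr::local_tempdir(), chunks = chunk_shape(32, 32, 8))
  out <- check_remote_equivalence(list(memory = mem, file = fx),
                                  steps = 60L, seed = 31L)
  expect_equal(out$identical, out$reads)
  expect_gt(out$reads, 0L)
})
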