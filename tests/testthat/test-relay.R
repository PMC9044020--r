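ramp_with_relay <- function(capacity = 64 * 1024^2, env = parent.frame()) {
  loaded <- ramp_loaded_remote("memory")
  relay <- caching_relay(loaded$remote, capacity_bytes = capacity)
  c(loaded, list(relay = relay))
}

test_that("LRU eviction follows the textbook access order", {
  cc <- lru_cache(2)                       # capacity: two 1-byte chunks
  cache_put(cc, "A", as.raw(1))
  cache_put(cc, "B", as.raw(2))
  cache_get(cc, "A")                       # A is now most recent
  ev <- cache_put(cc, "C", as.raw(3))
  expect_identical(as.character(ev), "B")
  expect_null(cache_get(cc, "B"))
  expect_false(is.null(cache_get(cc, "A")))

  cc2 <- lru_cache(3)
  for (k in c("A", "B", "C")) cache_put(cc2, k, as.raw(1))
  cache_get(cc2, "A")
  ev2 <- cache_put(cc2, "D", as.raw(4))
  expect_identical(as.character(ev2), "B")
})

test_that("an item exceeding the whole capacity is refused (pass-through)", {
  cc <- lru_cache(4)
  out <- cache_put(cc, "big", as.raw(1:10))
  expect_true(isTRUE(attr(out, "refused")))
  expect_equal(cache_stats(cc)$stored_bytes, 0)
  # and the relay still serves such requests correctly
  loaded <- ramp_loaded_remote("memory")
  tiny <- caching_relay(loaded$remote, capacity_bytes = 16)   # < one chunk
  req <- cutout_request(loaded$resource, c(0, 64), c(0, 64), c(0, 16))
  expect_identical(as.array(get_cutout(tiny, req)),
                   ramp_formula(c(0, 64), c(0, 64), c(0, 16)))
  expect_equal(cache_stats(tiny$tier)$stored_bytes, 0)
})

test_that("stored bytes never exceed capacity under random traffic", {
  loaded <- ramp_loaded_remote("memory")
  # room for ~6 chunks of 32*32*8 = 8192 B
  relay <- caching_relay(loaded$remote, capacity_bytes = 50000)
  local_rng(47)
  for (i in 1:40) {
    req <- random_request(loaded$resource)
    blk <- get_cutout(relay, req)
    expect_identical(blk$data, ramp_formula(req$x, req$y, req$z))
    expect_lte(cache_stats(relay$tier)$stored_bytes, relay$tier$capacity)
  }
  expect_gt(relay$tier$hits + relay$tier$misses, 0L)
})

test_that("cold requests miss once per touched chunk; warm requests hit with zero upstream calls", {
  x <- ramp_with_relay()
  req <- cutout_request(x$resource, c(5, 70), c(3, 64), c(2, 20))
  n_chunks <- chunks_touched(req, x$chunks)
  s0 <- relay_stats(x$relay)
  blk1 <- get_cutout(x$relay, req)
  s1 <- relay_stats(x$relay)
  expect_equal(s1$misses - s0$misses, n_chunks)
  expect_equal(s1$hits - s0$hits, 0)
  blk2 <- get_cutout(x$relay, req)
  s2 <- relay_stats(x$relay)
  expect_equal(s2$hits - s1$hits, n_chunks)
  expect_equal(s2$misses, s1$misses)
  expect_equal(s2$upstream_fetches, s1$upstream_fetches)  # zero upstream calls
  expect_identical(blk1$data, blk2$data)
  # accounting: hits + misses per request = chunks_touched
  expect_equal((s2$hits - s0$hits) + (s2$misses - s0$misses), 2 * n_chunks)
})

test_that("relay responses equal direct upstream responses on random requests", {
  x <- ramp_with_relay()
  local_rng(53)
  for (i in 1:40) {
    req <- random_request(x$resource)
    expect_identical(as.array(get_cutout(x$relay, req)),
                     as.array(get_cutout(x$remote, req)))
  }
})

test_that("daisy-chained relays (depth 3) stay transparent", {
  x <- ramp_with_relay()
  r2 <- caching_relay(x$relay, capacity_bytes = 64 * 1024^2)
  r3 <- caching_relay(r2, capacity_bytes = 64 * 1024^2)
  local_rng(59)
  for (i in 1:25) {
    req <- random_request(x$resource)
    expect_identical(as.array(get_cutout(r3, req)),
                     ramp_formula(req$x, req$y, req$z))
  }
  # a warm front tier answers without middle or back tiers being consulted
  req <- cutout_request(x$resource, c(0, 64), c(0, 64), c(0, 16))
  invisible(get_cutout(r3, req))
  mid <- r2$upstream_fetches
  invisible(get_cutout(r3, req))
  expect_equal(r2$upstream_fetches, mid)
})

test_that("writes through the relay invalidate and never serve stale data", {
  x <- ramp_with_relay()
  req <- cutout_request(x$resource, c(0, 40), c(0, 40), c(0, 12))
  invisible(get_cutout(x$relay, req))          # populate cache
  new_vals <- array(17L, c(40, 40, 12))
  post_cutout(x$relay, req, new_vals)
  expect_true(all(as.array(get_cutout(x$relay, req)) == 17L))
  # disjoint cached chunks are untouched by a box invalidation
  far <- cutout_request(x$resource, c(64, 96), c(64, 96), c(16, 24))
  invisible(get_cutout(x$relay, far))
  before <- cache_stats(x$relay$tier)$n_chunks
  removed <- invalidate(x$relay, x$resource, box = req)
  expect_equal(cache_stats(x$relay$tier)$n_chunks, before - removed)
  h0 <- relay_stats(x$relay)$hits
  invisible(get_cutout(x$relay, far))
  expect_equal(relay_stats(x$relay)$hits, h0 + chunks_touched(far, x$chunks))
})

test_that("invalidate(all) returns the cache to cold", {
  x <- ramp_with_relay()
  req <- cutout_request(x$resource, c(0, 64), c(0, 64), c(0, 16))
  invisible(get_cutout(x$relay, req))
  expect_gt(cache_stats(x$relay$tier)$n_chunks, 0)
  invalidate(x$relay)
  expect_equal(cache_stats(x$relay$tier)$n_chunks, 0)
  m0 <- relay_stats(x$relay)$misses
  invisible(get_cutout(x$relay, req))
  expect_equal(relay_stats(x$relay)$misses - m0, chunks_touched(req, x$chunks))
})

test_that("a relay with a dead upstream serves fully cached boxes and errors otherwise", {
  loaded <- ramp_loaded_remote("memory")
  hr_dead <- http_remote("http://127.0.0.1:1", timeout = 1, retries = 1L)
  relay <- caching_relay(loaded$remote, capacity_bytes = 64 * 1024^2)
  req <- cutout_request(loaded$resource, c(0, 32), c(0, 32), c(0, 8))
  invisible(get_cutout(relay, req))            # warm one chunk
  relay$upstream <- hr_dead                    # upstream goes away
  expect_identical(as.array(get_cutout(relay, req)),
                   ramp_formula(c(0, 32), c(0, 32), c(0, 8)))
  other <- cutout_request(loaded$resource, c(32, 64), c(0, 32), c(0, 8))
  expect_error(get_cutout(relay, other),
               class = "vk_upstream_unavailable_error")
})

test_that("an on-disk cache tier behaves like the in-memory tier", {
  dir <- withr::local_tempdir()
  loaded <- ramp_loaded_remote("memory")
  # room for all 8 chunks (8 x 8192 B) the request below touches
  relay <- caching_relay(loaded$remote, capacity_bytes = 128000, cache_dir = dir)
  req <- cutout_request(loaded$resource, c(0, 64), c(0, 64), c(0, 16))
  expect_identical(as.array(get_cutout(relay, req)),
                   ramp_formula(c(0, 64), c(0, 64), c(0, 16)))
  expect_gt(length(list.files(dir)), 0)
  h0 <- relay_stats(relay)$hits
  expect_identical(as.array(get_cutout(relay, req)),
                   ramp_formula(c(0, 64), c(0, 64), c(0, 16)))
  expect_equal(relay_stats(relay)$hits - h0, chunks_touched(req, chunk_shape(32, 32, 8)))
  expect_lte(cache_stats(relay$tier)$stored_bytes, relay$tier$capacity)
})

test_that("a relay served over HTTP answers the dialect and exposes cache stats", {
  srv <- local_empty_server()
  # load the upstream through HTTP, then put a relay server in front of it
  hr <- http_remote(srv$url)
  ch <- test_channel(c(64L, 64L, 16L))
  create_resource(hr, ch, chunks = chunk_shape(32, 32, 8))
  post_cutout(hr, cutout_request(ch, c(0, 64), c(0, 64), c(0, 16)),
              ramp_formula(c(0, 64), c(0, 64), c(0, 16)))
  rsrv <- local_relay_server(srv$root)
  rhr <- http_remote(rsrv$url)
  req <- cutout_request(ch, c(3, 50), c(5, 60), c(2, 14))
  expect_identical(as.array(get_cutout(rhr, req)),
                   ramp_formula(c(3, 50), c(5, 60), c(2, 14)))
  invisible(get_cutout(rhr, req))
  st <- fetch_relay_stats(rsrv$url)
  expect_gt(st$hits, 0)
  expect_equal(st$hits + st$misses, 2 * chunks_touched(req, chunk_shape(32, 32, 8)))
})
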