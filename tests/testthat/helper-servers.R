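# Background HTTP servers for tests.  Each helper registers teardown on the
# calling test's exit via withr::defer.

local_ramp_server <- function(extents = c(96L, 96L, 24L),
                              chunks = c(32L, 32L, 8L), writable = TRUE,
                              env = parent.frame()) {
  root <- withr::local_tempdir(.local_envir = env)
  fx <- file_chunk_remote(root, chunks = as.integer(chunks))
  ch <- test_channel(extents)
  create_resource(fx, ch, chunks = chunk_shape(chunks[1], chunks[2], chunks[3]))
  post_cutout(fx, cutout_request(ch, c(0L, extents[1]), c(0L, extents[2]),
                                 c(0L, extents[3])),
              ramp_formula(c(0L, extents[1]), c(0L, extents[2]), c(0L, extents[3])))
  srv <- start_server_process(list(type = "file", root = root,
                                   chunk_shape = as.integer(chunks)),
                              writable = writable)
  withr::defer(srv$process$kill(), envir = env)
  c(srv, list(resource = ch, root = root, direct = fx))
}

local_empty_server <- function(chunks = c(32L, 32L, 8L), writable = TRUE,
                               env = parent.frame()) {
  root <- withr::local_tempdir(.local_envir = env)
  srv <- start_server_process(list(type = "file", root = root,
                                   chunk_shape = as.integer(chunks)),
                              writable = writable)
  withr::defer(srv$process$kill(), envir = env)
  c(srv, list(root = root))
}

local_relay_server <- function(upstream_root, chunks = c(32L, 32L, 8L),
                               capacity_bytes = 64 * 1024^2,
                               env = parent.frame()) {
  srv <- start_server_process(list(type = "file", root = upstream_root,
                                   chunk_shape = as.integer(chunks)),
                              relay = list(capacity_bytes = capacity_bytes,
                                           cache_dir = NULL))
  withr::defer(srv$process$kill(), envir = env)
  srv
}

fetch_relay_stats <- function(url) {
  jsonlite::fromJSON(rawToChar(curl::curl_fetch_memory(
    paste0(url, "/v1/cache/stats"))$content))
}
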