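#' Reference cutout server
#'
#' Serves any remote over HTTP in a BossDB-flavored cutout REST dialect so
#' that the HTTP client remote ([http_remote()]), the caching relay, and
#' external tools can read (and optionally write) it.  Endpoints:
#'
#' ```
#' GET  /v1/ping                                        liveness
#' GET  /v1/capabilities                                JSON capability list
#' GET  /v1/resource/{path...}                          metadata JSON
#' POST /v1/resource/{path...}                          create (JSON body)
#' GET  /v1/list/{prefix...}                            child paths, JSON
#' GET  /v1/cutout/{path...}/{res}/{x0}:{x1}/{y0}:{y1}/{z0}:{z1}/
#' POST /v1/cutout/...  (same path, gzip raw payload)
#' ```
#'
#' `{path...}` is `collection/experiment/channel` for hierarchical resources
#' or a single component for data instances.  Cutout payloads are the raw
#' little-endian C-order (z, y, x) voxel bytes, gzip-compressed; the dtype is
#' the resource's.  Errors are JSON `{error, message}` with 400 (bad
#' request/bounds/dtype), 403 (capability), 404 (unknown resource) or 409
#' (already exists).
#'
#' @param remote The backing remote (any object with the read capability).
#' @param host,port Bind address.  `port = 0` picks a random free port.
#' @param writable If `FALSE` the server declares only read capability and
#'   refuses writes and creates.
#' @return `serve_reference()` blocks, running the event loop until
#'   interrupted.  `reference_app()` returns the httpuv app object (exposed
#'   for embedding and tests).
#' @seealso [serve_relay()] for the caching relay sharing this dialect.
#' @export
serve_reference <- function(remote, host = "127.0.0.1", port = 8680,
                            writable = TRUE) {
  app <- reference_app(remote, writable = writable)
  httpuv::runServer(host, port, app)
}

#' @rdname serve_reference
#' @export
reference_app <- function(remote, writable = TRUE) {
  list(call = function(req) handle_request(remote, req, writable))
}

http_error_status <- function(kind) {
  switch(kind,
         not_found = 404L,
         already_exists = 409L,
         capability = 403L,
         bounds = 400L, empty_range = 400L, resolution = 400L,
         dtype = 400L, shape = 400L, usage = 400L,
         500L)
}

json_response <- function(status, body) {
  list(status = status,
       headers = list("Content-Type" = "application/json"),
       body = jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA))
}

error_response <- function(cond) {
  kind <- vk_error_kind(cond)
  json_response(http_error_status(kind),
                list(error = kind, message = conditionMessage(cond)))
}

parse_range_token <- function(tok, axis) {
  m <- regmatches(tok, regexec("^([0-9]+):([0-9]+)$", tok))[[1]]
  if (length(m) != 3L)
    vk_stop("usage", "malformed %s range '%s' (expected start:stop)", axis, tok)
  c(as.integer(m[2]), as.integer(m[3]))
}

# resolve a slash path (1 or 3 components) into a resource stub for lookup
resource_from_path <- function(parts) {
  if (length(parts) == 1L) data_instance_resource(parts, "image", "uint8")
  else if (length(parts) == 3L) channel_resource(parts[1], parts[2], parts[3])
  else vk_stop("usage", "resource paths take 1 (instance) or 3 (channel) components")
}

handle_request <- function(remote, req, writable) {
  tryCatch({
    path <- req$PATH_INFO
    method <- req$REQUEST_METHOD
    parts <- strsplit(sub("^/", "", path), "/", fixed = TRUE)[[1]]
    parts <- parts[nzchar(parts)]
    if (length(parts) < 2L || parts[1] != "v1")
      return(json_response(404L, list(error = "not_found", message = "unknown route")))
    route <- parts[2]
    rest <- parts[-(1:2)]
    if (route == "ping") return(json_response(200L, list(status = "ok")))
    if (route == "capabilities") {
      caps <- remote_capabilities(remote)
      if (!writable) caps <- intersect(caps, c("read", "list", "mesh_server_side"))
      return(json_response(200L, list(capabilities = as.list(caps))))
    }
    if (route == "cache" && length(rest) == 1L && rest[1] == "stats")
      return(handle_cache_stats(remote))
    if (route == "resource") return(handle_resource(remote, req, rest, method, writable))
    if (route == "list") {
      prefix <- paste(rest, collapse = "/")
      return(json_response(200L, list(resources = as.list(list_resources(remote, prefix)))))
    }
    if (route == "cutout") return(handle_cutout(remote, req, rest, method, writable))
    json_response(404L, list(error = "not_found", message = "unknown route"))
  }, vk_error = error_response,
     error = function(e) json_response(500L,
       list(error = "runtime", message = conditionMessage(e))))
}

handle_cache_stats <- function(remote) {
  if (!inherits(remote, "vk_relay"))
    return(json_response(404L, list(error = "not_found",
                                    message = "not a caching relay")))
  json_response(200L, relay_stats(remote))
}

handle_resource <- function(remote, req, rest, method, writable) {
  res <- resource_from_path(rest)
  if (method == "GET") {
    meta <- get_metadata(remote, res)
    body <- list(kind = meta$resource$kind, path = meta$resource$path,
                 channel_kind = meta$channel_kind, dtype = meta$dtype,
                 frame = frame_to_list(meta$frame),
                 chunks = as.integer(meta$chunks))
    return(json_response(200L, body))
  }
  if (method == "POST") {
    if (!writable) vk_stop("capability", "server is read-only")
    body <- jsonlite::fromJSON(rawToChar(req$rook.input$read()))
    frame <- frame_from_list(body$frame)
    res <- if (length(rest) == 1L)
      data_instance_resource(rest, body$channel_kind, body$dtype, frame)
    else
      channel_resource(rest[1], rest[2], rest[3], body$channel_kind, body$dtype, frame)
    chunks <- if (!is.null(body$chunks)) as_chunk_shape(unlist(body$chunks))
              else default_chunk_shape()
    create_resource(remote, res, frame, chunks)
    return(json_response(201L, list(status = "created")))
  }
  json_response(405L, list(error = "usage", message = "unsupported method"))
}

handle_cutout <- function(remote, req, rest, method, writable) {
  if (length(rest) < 5L)
    vk_stop("usage", "cutout path needs resource, resolution and three ranges")
  n <- length(rest)
  res_parts <- rest[seq_len(n - 4L)]
  resolution <- suppressWarnings(as.integer(rest[n - 3L]))
  if (is.na(resolution)) vk_stop("usage", "bad resolution '%s'", rest[n - 3L])
  xr <- parse_range_token(rest[n - 2L], "x")
  yr <- parse_range_token(rest[n - 1L], "y")
  zr <- parse_range_token(rest[n], "z")
  stub <- resource_from_path(res_parts)
  meta <- get_metadata(remote, stub)
  request <- cutout_request(meta$resource, xr, yr, zr, resolution)
  if (method == "GET") {
    block <- get_cutout(remote, request)
    payload <- memCompress(encode_voxels(as.array(block), meta$dtype), "gzip")
    return(list(status = 200L,
                headers = list("Content-Type" = "application/octet-stream"),
                body = payload))
  }
  if (method == "POST") {
    if (!writable) vk_stop("capability", "server is read-only")
    raw_body <- req$rook.input$read()
    bytes <- memDecompress(raw_body, "gzip")
    validate_request(request, meta$frame)
    data <- decode_volume(bytes, request_shape(request), meta$dtype)
    post_cutout(remote, request, data)
    return(json_response(201L, list(status = "ok")))
  }
  json_response(405L, list(error = "usage", message = "unsupported method"))
}

#' Run a server in a background process
#'
#' Convenience wrapper used by tests, examples and the CLI: starts
#' [serve_reference()] or [serve_relay()] in a `callr` background R process
#' serving a remote reconstructed from a config entry (see
#' [remote_from_config()]), waits until `/v1/ping` answers, and returns a
#' handle.
#'
#' @param config A remote config entry (list with `type` etc.).
#' @param port Port to bind; default picks a random free port.
#' @param writable Passed to [serve_reference()].
#' @param relay Optional list of relay settings (`capacity_bytes`,
#'   `cache_dir`): when given, the child runs a caching relay whose upstream
#'   is the configured remote.
#' @return A list with `url`, `port`, and `process` (a `callr` handle; call
#'   `$kill()` when done).
#' @export
start_server_process <- function(config, port = NULL, writable = TRUE,
                                 relay = NULL) {
  if (!requireNamespace("callr", quietly = TRUE))
    vk_stop("runtime", "background servers require the callr package")
  if (is.null(port)) port <- httpuv::randomPort()
  px <- callr::r_bg(function(config, port, writable, relay) {
    remote <- voxelkit::remote_from_config(config)
    if (!is.null(relay)) {
      rl <- voxelkit::caching_relay(remote,
                                    capacity_bytes = relay$capacity_bytes,
                                    cache_dir = relay$cache_dir)
      voxelkit::serve_relay(rl, port = port, writable = writable)
    } else {
      voxelkit::serve_reference(remote, port = port, writable = writable)
    }
  }, args = list(config = config, port = port, writable = writable,
                 relay = relay), supervise = TRUE)
  url <- sprintf("http://127.0.0.1:%d", port)
  wait_for_server(url, px)
  list(url = url, port = port, process = px)
}

wait_for_server <- function(url, px, timeout = 15) {
  t0 <- Sys.time()
  repeat {
    ok <- tryCatch({
      r <- curl::curl_fetch_memory(paste0(url, "/v1/ping"))
      r$status_code == 200L
    }, error = function(e) FALSE)
    if (ok) return(invisible(TRUE))
    if (!px$is_alive()) {
      err <- tryCatch(px$read_all_error(), error = function(e) "")
      vk_stop("runtime", "server process died during startup: %s", err)
    }
    if (as.numeric(Sys.time() - t0, units = "secs") > timeout)
      vk_stop("runtime", "server at %s did not come up within %gs", url, timeout)
    Sys.sleep(0.05)
  }
}
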