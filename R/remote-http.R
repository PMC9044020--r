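#' HTTP cutout-service remote
#'
#' A client for the cutout REST dialect spoken by [serve_reference()] and
#' [serve_relay()].  Capabilities are whatever the server declares (queried
#' once at construction).  Cutout reads are decomposed into the server's
#' chunk-aligned blocks and fetched serially or in parallel; idempotent GETs
#' are retried with exponential backoff, POSTs are never auto-retried.
#'
#' @param base_url Server base URL, e.g. `"http://127.0.0.1:8680"`.
#' @param timeout Per-request timeout in seconds.
#' @param retries Maximum GET attempts on transport failure.
#' @return A remote of class `vk_http_remote`.
#' @export
http_remote <- function(base_url, timeout = 30, retries = 3L) {
  self <- new.env(parent = emptyenv())
  self$base_url <- sub("/+$", "", base_url)
  self$timeout <- timeout
  self$retries <- as.integer(retries)
  self$meta_cache <- new.env(parent = emptyenv())
  class(self) <- c("vk_http_remote", "vk_remote")
  self$capabilities <- tryCatch({
    r <- http_get(self, "/v1/capabilities")
    unlist(jsonlite::fromJSON(rawToChar(r$content))$capabilities)
  }, error = function(e) "read")
  self
}

http_url <- function(remote, path) paste0(remote$base_url, path)

http_get <- function(remote, path) {
  attempt <- 0L
  repeat {
    attempt <- attempt + 1L
    out <- tryCatch({
      h <- curl::new_handle(timeout = remote$timeout)
      curl::curl_fetch_memory(http_url(remote, path), handle = h)
    }, error = function(e) e)
    if (!inherits(out, "error")) {
      if (out$status_code >= 400L) http_raise(out)
      return(out)
    }
    if (attempt >= remote$retries)
      vk_stop("upstream_unavailable", "GET %s failed after %d attempts: %s",
              path, attempt, conditionMessage(out))
    Sys.sleep(0.2 * 2^(attempt - 1L))
  }
}

http_post <- function(remote, path, body, content_type = "application/octet-stream") {
  h <- curl::new_handle(timeout = remote$timeout)
  curl::handle_setopt(h, customrequest = "POST", postfields = body,
                      postfieldsize = length(body))
  curl::handle_setheaders(h, "Content-Type" = content_type)
  out <- tryCatch(curl::curl_fetch_memory(http_url(remote, path), handle = h),
                  error = function(e)
                    vk_stop("upstream_unavailable", "POST %s failed: %s",
                            path, conditionMessage(e)))
  if (out$status_code >= 400L) http_raise(out)
  out
}

# re-raise a server-side JSON error as the matching classed condition
http_raise <- function(response) {
  kind <- "runtime"; msg <- sprintf("HTTP %d", response$status_code)
  body <- tryCatch(jsonlite::fromJSON(rawToChar(response$content)),
                   error = function(e) NULL)
  if (!is.null(body$error)) kind <- body$error
  if (!is.null(body$message)) msg <- body$message
  vk_stop(kind, "%s", msg)
}

#' @export
remote_capabilities.vk_http_remote <- function(remote) remote$capabilities

res_url_path <- function(resource) {
  if (is.character(resource)) resource <- parse_resource_uri(resource)
  resource_path(resource)
}

#' @export
get_metadata.vk_http_remote <- function(remote, resource) {
  path <- res_url_path(resource)
  cached <- remote$meta_cache[[path]]
  if (!is.null(cached)) return(cached)
  r <- http_get(remote, paste0("/v1/resource/", path))
  m <- jsonlite::fromJSON(rawToChar(r$content))
  frame <- frame_from_list(m$frame)
  res <- if (m$kind == "data_instance")
    data_instance_resource(m$path, m$channel_kind, m$dtype, frame)
  else
    channel_resource(m$path[1], m$path[2], m$path[3], m$channel_kind, m$dtype, frame)
  meta <- list(resource = res, frame = frame, dtype = m$dtype,
               channel_kind = m$channel_kind, chunks = as_chunk_shape(m$chunks))
  remote$meta_cache[[path]] <- meta
  meta
}

#' @export
create_resource.vk_http_remote <- function(remote, resource,
                                           frame = resource$frame,
                                           chunks = default_chunk_shape()) {
  require_capability(remote, "create")
  if (is.null(frame)) vk_stop("usage", "a coordinate frame is required")
  body <- charToRaw(jsonlite::toJSON(
    list(channel_kind = resource$channel_kind, dtype = resource$dtype,
         frame = frame_to_list(frame), chunks = as.integer(as_chunk_shape(chunks))),
    auto_unbox = TRUE, digits = NA))
  http_post(remote, paste0("/v1/resource/", resource_path(resource)), body,
            "application/json")
  resource$frame <- frame
  invisible(resource)
}

cutout_path <- function(resource, request) {
  sprintf("/v1/cutout/%s/%d/%d:%d/%d:%d/%d:%d/",
          res_url_path(resource), request$resolution,
          request$x[1], request$x[2], request$y[1], request$y[2],
          request$z[1], request$z[2])
}

# Parallel HTTP fetches multiplex concurrent transfers on one event loop
# (curl's multi interface) rather than forking: network concurrency without
# any shared-socket hazards, and bit-identical output for any worker count.
#' @export
get_cutout.vk_http_remote <- function(remote, request, workers = 1L) {
  meta <- get_metadata(remote, request$resource)
  validate_request(request, meta$frame)
  ext <- extents_at(meta$frame, request$resolution)
  request$resource <- meta$resource
  plan <- decompose(request, meta$chunks)
  n <- nrow(plan)
  boxes <- lapply(seq_len(n), function(r) chunk_box(plan, r, ext))
  paths <- vapply(seq_len(n), function(r) {
    box <- boxes[[r]]
    sub <- cutout_request(meta$resource,
                          c(box$start[1], box$stop[1]),
                          c(box$start[2], box$stop[2]),
                          c(box$start[3], box$stop[3]), request$resolution)
    cutout_path(meta$resource, sub)
  }, character(1))
  payloads <- vector("list", n)
  if (workers > 1L && n > 1L) {
    pool <- curl::new_pool(total_con = workers, host_con = workers)
    for (r in seq_len(n)) {
      local({
        rr <- r
        h <- curl::new_handle(timeout = remote$timeout,
                              url = http_url(remote, paths[rr]))
        curl::multi_add(h,
          done = function(res) {
            if (res$status_code < 400L) payloads[[rr]] <<- res$content
          },
          fail = function(msg) NULL,
          pool = pool)
      })
    }
    curl::multi_run(pool = pool)
  }
  unpack <- function(r, content) {
    bytes <- memDecompress(content, "gzip")
    box <- boxes[[r]]
    sh <- box$stop - box$start
    clipped <- decode_volume(bytes, sh, meta$dtype)
    full <- new_volume_array(attr(plan, "chunks"), meta$dtype)
    full[seq_len(sh[1]), seq_len(sh[2]), seq_len(sh[3])] <- clipped
    full
  }
  blocks <- vector("list", n)
  for (r in seq_len(n)) {
    # anything the pooled pass did not deliver falls back to a plain
    # (retrying) GET; this also covers the serial workers = 1 path
    content <- payloads[[r]] %||% http_get(remote, paths[r])$content
    blocks[[r]] <- unpack(r, content)
  }
  names(blocks) <- plan$key
  stitch(plan, blocks)
}

#' @export
post_cutout.vk_http_remote <- function(remote, request, data) {
  require_capability(remote, "write")
  meta <- get_metadata(remote, request$resource)
  data <- check_write(meta, request, data)
  payload <- memCompress(encode_voxels(data, meta$dtype), "gzip")
  http_post(remote, cutout_path(meta$resource, request), payload)
  invisible(remote)
}

#' @export
list_resources.vk_http_remote <- function(remote, prefix = "") {
  path <- if (nzchar(prefix)) paste0("/v1/list/", prefix) else "/v1/list"
  r <- http_get(remote, path)
  out <- jsonlite::fromJSON(rawToChar(r$content))$resources
  if (!length(out)) character(0) else unlist(out)
}
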