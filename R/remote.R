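#' The Remote trait
#'
#' Remotes represent volumetric data stores: in-memory arrays
#' ([memory_remote()]), on-disk chunked files ([file_chunk_remote()]), HTTP
#' cutout services ([http_remote()]), and caching relays ([caching_relay()]).
#' Every remote supports at minimum volumetric reads ([get_cutout()]); it may
#' additionally declare `write`, `create`, `list`, or `mesh_server_side`
#' capabilities.  Services are written against the trait, so any remote
#' holding the same voxels produces the same service output.
#'
#' @param remote A remote object.
#' @return `remote_capabilities()` returns a character vector drawn from
#'   `c("read", "write", "create", "list", "mesh_server_side")`.
#' @name remote-trait
NULL

#' @rdname remote-trait
#' @export
remote_capabilities <- function(remote) UseMethod("remote_capabilities")

#' @rdname remote-trait
#' @param capability A capability name.
#' @export
has_capability <- function(remote, capability) {
  capability %in% remote_capabilities(remote)
}

require_capability <- function(remote, capability) {
  if (!has_capability(remote, capability))
    vk_stop("capability", "remote lacks the '%s' capability", capability)
  invisible(remote)
}

#' Service contracts and capability dispatch
#'
#' A service declares the remote capabilities it needs; [capability_check()]
#' reports whether a remote satisfies a service.  This is how a service picks
#' server-side execution when a remote offers it and falls back to its local
#' surrogate otherwise (see [mesh_for_id()]).
#'
#' @param required Character vector of required capabilities.
#' @return `service_contract()` returns a `vk_service` object;
#'   `capability_check()` a logical scalar.
#' @examples
#' svc <- service_contract("read")
#' capability_check(memory_remote(), svc)
#' @export
service_contract <- function(required = "read") {
  structure(list(required_resources = as.character(required)),
            class = "vk_service")
}

#' @rdname service_contract
#' @param remote A remote object, or a character vector of capabilities.
#' @param service A `vk_service` contract.
#' @export
capability_check <- function(remote, service) {
  caps <- if (is.character(remote)) remote else remote_capabilities(remote)
  all(service$required_resources %in% caps)
}

#' Create a resource on a remote
#'
#' Registers a channel or data-instance resource (parents are created
#' implicitly) with its coordinate frame and chunk shape.  A fresh resource
#' reads as all zeros everywhere.
#'
#' @param remote A remote with the `create` capability.
#' @param resource A channel or data-instance `vk_resource`.
#' @param frame The resource's [coordinate_frame()]; defaults to the one
#'   attached to the resource.
#' @param chunks Chunk shape for chunked backends.
#' @return The resource, with frame attached, invisibly.
#' @export
create_resource <- function(remote, resource, frame = resource$frame,
                            chunks = default_chunk_shape()) {
  UseMethod("create_resource")
}

#' Read a cutout
#'
#' Returns the voxel-exact dense subvolume named by the request.  Chunked
#' remotes decompose the request ([decompose()]), fetch the touched chunks
#' (serially or with `workers` forked fetchers), and [stitch()] the result;
#' the output is identical for any worker count.
#'
#' @param remote A remote with the `read` capability.
#' @param request A `vk_request`.
#' @param workers Number of parallel chunk fetchers.
#' @return A `vk_block`.
#' @export
get_cutout <- function(remote, request, workers = 1L) UseMethod("get_cutout")

#' Write a cutout
#'
#' Uploads a dense array into the request's box.  Shape and dtype must match
#' exactly; mismatched dtypes are rejected, never cast (silent casts corrupt
#' label volumes).  Overlapping writes are last-writer-wins.
#'
#' @inheritParams get_cutout
#' @param data 3D array of the request's shape.
#' @return The remote, invisibly.
#' @export
post_cutout <- function(remote, request, data) UseMethod("post_cutout")

#' List resources under a path prefix
#'
#' @param remote A remote with the `list` capability.
#' @param prefix Slash-joined partial path (`""` lists collections and data
#'   instances).
#' @return Lexicographically sorted character vector of child paths.
#' @export
list_resources <- function(remote, prefix = "") UseMethod("list_resources")

#' Resource metadata held by a remote
#'
#' @param remote A remote with the `read` capability.
#' @param resource A `vk_resource` (or its URI string).
#' @return A list with elements `resource` (with frame attached), `frame`,
#'   `dtype`, `channel_kind`, and `chunks`.
#' @export
get_metadata <- function(remote, resource) UseMethod("get_metadata")

as_resource_uri <- function(resource) {
  if (is.character(resource)) resource else resource_uri(resource)
}

# shared pre-write checks; returns data coerced to the resource dtype
check_write <- function(meta, request, data) {
  validate_request(request, meta$frame)
  shape <- request_shape(request)
  if (length(dim(data)) != 3L || !all(dim(data) == shape))
    vk_stop("shape", "data shape (%s) does not match request shape (%s)",
            paste(dim(data), collapse = "x"), paste(shape, collapse = "x"))
  dt <- attr(data, "vk_dtype")
  if (!is.null(dt) && dt != meta$dtype)
    vk_stop("dtype", "cannot write %s data into a %s resource", dt, meta$dtype)
  if (is.double(data) && meta$dtype != "uint64" && any(data != floor(data)))
    vk_stop("dtype", "non-integer data for %s resource", meta$dtype)
  coerce_voxels(data, meta$dtype)
}

#' Tag an array with an explicit voxel dtype
#'
#' Writes check the tag (when present) against the target resource's dtype
#' and refuse mismatches.
#'
#' @param data An array.
#' @param dtype A dtype name from [vk_dtypes()].
#' @return `data` with a dtype tag attribute.
#' @export
with_dtype <- function(data, dtype) {
  dtype_info(dtype)
  attr(data, "vk_dtype") <- dtype
  data
}

#' Randomized read/write equivalence check across remotes
#'
#' Runs one seeded script of resource creations, cutout writes and cutout
#' reads against several remotes in lockstep and verifies that every read
#' returns bit-identical voxels on all of them.  This is the operational
#' meaning of the remote trait: storage backends are interchangeable.
#'
#' @param remotes Named list of remotes, all supporting read/write/create.
#' @param steps Number of script steps.
#' @param seed Integer seed for the script.
#' @param extents Extents of the scratch channel used by the script.
#' @param dtype Voxel dtype exercised.
#' @return Invisibly, a list with `steps`, `reads`, and `identical` (number of
#'   read steps on which all remotes agreed).  Disagreement raises an error
#'   naming the step.
#' @export
check_remote_equivalence <- function(remotes, steps = 200L, seed = 1L,
                                     extents = c(96L, 96L, 24L),
                                     dtype = "uint8") {
  stopifnot(length(remotes) >= 2L)
  frame <- coordinate_frame(extents)
  res <- channel_resource("equiv", "script", "vol",
                          channel_kind = "image", dtype = dtype, frame = frame)
  for (r in remotes) create_resource(r, res, frame, chunks = chunk_shape(32, 32, 8))
  rng <- local_rng(seed)
  rand_box <- function() {
    s <- vapply(extents, function(e) {
      a <- sample.int(e, 1L) - 1L
      b <- a + sample.int(e - a, 1L)
      c(a, b)
    }, integer(2))
    cutout_request(res, s[, 1], s[, 2], s[, 3])
  }
  reads <- 0L; agreed <- 0L
  info <- dtype_info(dtype)
  for (step in seq_len(steps)) {
    if (runif(1) < 0.4) {
      req <- rand_box()
      vals <- array(sample.int(min(info$max, 2^15) + 1L, prod(request_shape(req)),
                               replace = TRUE) - 1L,
                    dim = request_shape(req))
      for (r in remotes) post_cutout(r, req, vals)
    } else {
      req <- rand_box()
      reads <- reads + 1L
      outs <- lapply(remotes, function(r) as.array(get_cutout(r, req)))
      ok <- all(vapply(outs[-1], identical, logical(1), y = outs[[1]]))
      if (!ok)
        vk_stop("runtime", "remotes disagreed at step %d", step)
      agreed <- agreed + 1L
    }
  }
  invisible(list(steps = steps, reads = reads, identical = agreed))
}

# seeded RNG scope: saves and restores .Random.seed on exit of the calling
# frame, so fixtures and scripts have no hidden global side effects
local_rng <- function(seed, envir = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  assign(".vk_saved_seed", old, envir = envir)
  restore <- quote({
    if (!is.null(.vk_saved_seed))
      assign(".Random.seed", .vk_saved_seed, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  do.call(on.exit, list(restore, add = TRUE), envir = envir)
  set.seed(seed)
  invisible(seed)
}
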