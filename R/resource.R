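#' Resources: addressable units of data
#'
#' A resource points at an atomic unit or grouping of data inside a remote.
#' Two addressing schemes are supported: the hierarchical
#' collection/experiment/channel triple used by cloud-scale stores, and a flat
#' single-name data instance.  Channels and data instances carry a channel
#' kind (`"image"` or `"annotation"`), a voxel dtype, and optionally a
#' [coordinate_frame()].  Annotation channels always hold `uint64` labels;
#' image channels hold `uint8` or `uint16` intensities.
#'
#' @param collection,experiment,channel Path components (non-empty, no
#'   separators or whitespace).
#' @param channel_kind `"image"` or `"annotation"`.
#' @param dtype Voxel dtype; defaults to `"uint8"` for image channels and
#'   `"uint64"` for annotation channels.
#' @param frame Optional [coordinate_frame()].
#' @return An object of class `vk_resource`.
#' @examples
#' ch <- channel_resource("mouse1", "cortex", "em", "image", "uint8")
#' resource_uri(ch)
#' @export
channel_resource <- function(collection, experiment, channel,
                             channel_kind = "image", dtype = NULL,
                             frame = NULL) {
  new_resource("channel", c(collection, experiment, channel),
               channel_kind, dtype, frame)
}

#' @rdname channel_resource
#' @param name Data-instance name.
#' @param version Opaque version tag, accepted syntactically; only one version
#'   is ever stored.
#' @export
data_instance_resource <- function(name, channel_kind = "image", dtype = NULL,
                                   frame = NULL, version = NULL) {
  res <- new_resource("data_instance", name, channel_kind, dtype, frame)
  res$version <- version
  res
}

#' @rdname channel_resource
#' @export
collection_resource <- function(collection) {
  new_resource("collection", collection, NULL, NULL, NULL)
}

#' @rdname channel_resource
#' @export
experiment_resource <- function(collection, experiment) {
  new_resource("experiment", c(collection, experiment), NULL, NULL, NULL)
}

new_resource <- function(kind, path, channel_kind, dtype, frame) {
  path <- as.character(path)
  if (!length(path) || any(!nzchar(path)) ||
      any(grepl("[/\\\\[:space:]]", path)) || anyNA(path))
    vk_stop("usage", "resource path components must be non-empty, with no path separators or whitespace")
  n_expect <- switch(kind, collection = 1L, experiment = 2L,
                     channel = 3L, data_instance = 1L,
                     vk_stop("usage", "unknown resource kind '%s'", kind))
  if (length(path) != n_expect)
    vk_stop("usage", "a %s resource takes exactly %d path component(s)", kind, n_expect)
  if (kind %in% c("channel", "data_instance")) {
    if (!channel_kind %in% c("image", "annotation"))
      vk_stop("usage", "channel_kind must be 'image' or 'annotation'")
    if (is.null(dtype))
      dtype <- if (channel_kind == "annotation") "uint64" else "uint8"
    if (channel_kind == "annotation" && dtype != "uint64")
      vk_stop("dtype", "annotation channels must be uint64, got %s", dtype)
    if (channel_kind == "image" && !dtype %in% c("uint8", "uint16"))
      vk_stop("dtype", "image channels must be uint8 or uint16, got %s", dtype)
    dtype_info(dtype)
  } else {
    channel_kind <- NULL
    dtype <- NULL
  }
  if (!is.null(frame) && !inherits(frame, "vk_frame"))
    vk_stop("usage", "frame must be a coordinate_frame()")
  structure(
    list(kind = kind, path = path, channel_kind = channel_kind,
         dtype = dtype, frame = frame),
    class = "vk_resource"
  )
}

#' @export
print.vk_resource <- function(x, ...) {
  extra <- if (!is.null(x$dtype)) sprintf(" [%s %s]", x$channel_kind, x$dtype) else ""
  cat(sprintf("<vk_resource %s> %s%s\n", x$kind, resource_uri(x), extra))
  invisible(x)
}

#' Canonical resource URIs
#'
#' Channels (and their parents) serialize as
#' `bosslike://collection/experiment/channel`; data instances as
#' `instance://name`.  [parse_resource_uri()] is the exact inverse on the path
#' part (channel kind, dtype and frame are remote-side metadata and are not
#' encoded in the URI).
#'
#' @param resource A `vk_resource`.
#' @return A character URI.
#' @export
resource_uri <- function(resource) {
  if (resource$kind == "data_instance")
    paste0("instance://", resource$path)
  else
    paste0("bosslike://", paste(resource$path, collapse = "/"))
}

#' @rdname resource_uri
#' @param uri A URI string as produced by [resource_uri()].
#' @param channel_kind,dtype Optional metadata to attach to the parsed
#'   resource.
#' @export
parse_resource_uri <- function(uri, channel_kind = "image", dtype = NULL) {
  if (startsWith(uri, "instance://")) {
    name <- sub("^instance://", "", uri)
    return(data_instance_resource(name, channel_kind, dtype))
  }
  if (startsWith(uri, "bosslike://")) {
    parts <- strsplit(sub("^bosslike://", "", uri), "/", fixed = TRUE)[[1]]
    parts <- parts[nzchar(parts)]
    return(switch(as.character(length(parts)),
      "1" = collection_resource(parts[1]),
      "2" = experiment_resource(parts[1], parts[2]),
      "3" = channel_resource(parts[1], parts[2], parts[3], channel_kind, dtype),
      vk_stop("usage", "bosslike:// URIs take 1-3 path components")))
  }
  vk_stop("usage", "unrecognized resource URI '%s'", uri)
}

# slash-joined path (no scheme), used for listing and on-disk layout
resource_path <- function(resource) paste(resource$path, collapse = "/")
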