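#' Application configuration
#'
#' The CLI (and any embedding code) names its remotes in a YAML config file:
#'
#' ```yaml
#' remotes:
#'   store:
#'     type: file            # memory | file | http
#'     root: /data/volumes   # file remotes
#'     chunk_shape: [512, 512, 16]
#'   api:
#'     type: http
#'     url: http://127.0.0.1:8680
#' default_workers: 4
#' log_level: info
#' cache:
#'   capacity_bytes: 134217728
#'   dir: /tmp/vk-cache
#' ```
#'
#' Unknown keys are rejected (naming the key), and every named remote must be
#' constructible at load time.
#'
#' @param path Path to the YAML file.
#' @return A validated config list of class `vk_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) vk_stop("config", "config file '%s' not found", path)
  cfg <- yaml::read_yaml(path)
  known_top <- c("remotes", "default_workers", "log_level", "cache")
  bad <- setdiff(names(cfg), known_top)
  if (length(bad)) vk_stop("config", "unknown config key '%s'", bad[1])
  cfg$remotes <- cfg$remotes %||% list()
  known_remote <- c("type", "root", "url", "chunk_shape", "timeout", "retries")
  for (nm in names(cfg$remotes)) {
    entry <- cfg$remotes[[nm]]
    bad <- setdiff(names(entry), known_remote)
    if (length(bad))
      vk_stop("config", "unknown config key 'remotes.%s.%s'", nm, bad[1])
    if (is.null(entry$type) || !entry$type %in% c("memory", "file", "http"))
      vk_stop("config", "remote '%s' needs type memory, file or http", nm)
    if (entry$type == "file" && is.null(entry$root))
      vk_stop("config", "file remote '%s' needs a root", nm)
    if (entry$type == "http" && is.null(entry$url))
      vk_stop("config", "http remote '%s' needs a url", nm)
  }
  cfg$default_workers <- cfg$default_workers %||% 4L
  structure(cfg, class = "vk_config")
}

#' Construct a remote from a config entry
#'
#' @param entry A list with `type` (`"memory"`, `"file"` or `"http"`) and the
#'   type's fields (`root`, `url`, `chunk_shape`, `timeout`, `retries`).
#' @return A remote object.
#' @export
remote_from_config <- function(entry) {
  chunks <- if (!is.null(entry$chunk_shape)) as_chunk_shape(unlist(entry$chunk_shape))
            else default_chunk_shape()
  switch(entry$type %||% "",
         memory = memory_remote(chunks = chunks),
         file = file_chunk_remote(entry$root, chunks = chunks),
         http = http_remote(entry$url, timeout = entry$timeout %||% 30,
                            retries = entry$retries %||% 3L),
         vk_stop("config", "unknown remote type '%s'", entry$type %||% "<missing>"))
}

#' @rdname remote_from_config
#' @param config A `vk_config` from [load_config()].
#' @param name Remote name in the config.
#' @export
config_remote <- function(config, name) {
  entry <- config$remotes[[name]]
  if (is.null(entry)) vk_stop("config", "no remote named '%s' in config", name)
  remote_from_config(entry)
}

# structured stderr logging: timestamp level module event key=value ...
vk_log <- function(module, event, ..., level = "info") {
  verbose <- isTRUE(getOption("voxelkit.verbose", FALSE))
  if (!verbose && !level %in% c("warn", "error")) return(invisible())
  kv <- list(...)
  tail <- if (length(kv))
    paste(sprintf("%s=%s", names(kv), vapply(kv, format, character(1))),
          collapse = " ")
  else ""
  message(sprintf("%s %s %s %s %s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), level, module,
                  event, tail))
  invisible()
}
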