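# Classed error conditions used across the package.  Every user-facing error
# carries a class "vk_<kind>_error" so callers (and the HTTP layer, which maps
# kinds onto status codes) can dispatch on the failure mode rather than on
# message text.

vk_stop <- function(kind, fmt, ..., data = list()) {
  msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
  cond <- structure(
    class = c(sprintf("vk_%s_error", kind), "vk_error", "error", "condition"),
    c(list(message = msg, call = sys.call(-1)), data)
  )
  stop(cond)
}

#' @export
print.vk_error <- function(x, ...) {
  cat(sprintf("<%s> %s\n", class(x)[1], conditionMessage(x)))
  invisible(x)
}

# kind of a vk_error condition, e.g. "bounds" from "vk_bounds_error"
vk_error_kind <- function(cond) {
  cls <- grep("^vk_.*_error$", class(cond), value = TRUE)
  if (!length(cls)) return("runtime")
  sub("^vk_(.*)_error$", "\\1", cls[1])
}
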