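#' Coordinate frame of a volumetric channel
#'
#' A coordinate frame records the voxel extents of one channel at resolution 0,
#' the physical size of a voxel along each axis, and the resolution pyramid:
#' each level divides X and Y extents by `downsample_factor` (Z is exempt by
#' default, the usual convention for anisotropic serial-section EM, but can be
#' included for isotropic volumes).
#'
#' @param extents Integer vector of length 3: voxel counts along X, Y, Z at
#'   resolution 0.
#' @param voxel_size Positive numeric vector of length 3: physical size of a
#'   voxel along X, Y, Z, in `unit`s.
#' @param unit Unit tag for `voxel_size` (default `"nm"`).
#' @param num_resolutions Number of resolution levels (>= 1).
#' @param downsample_factor Integer factor between successive levels.
#' @param isotropic If `TRUE`, Z is downsampled like X and Y.
#' @return An object of class `vk_frame`.
#' @examples
#' fr <- coordinate_frame(c(1024, 1024, 64), voxel_size = c(4, 4, 40))
#' extents_at(fr, 0)
#' @export
coordinate_frame <- function(extents, voxel_size = c(1, 1, 1), unit = "nm",
                             num_resolutions = 1L, downsample_factor = 2L,
                             isotropic = FALSE) {
  extents <- as.integer(extents)
  if (length(extents) != 3L || any(is.na(extents)) || any(extents < 0L))
    vk_stop("usage", "extents must be three non-negative integers")
  voxel_size <- as.double(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    vk_stop("usage", "voxel_size must be three positive reals")
  num_resolutions <- as.integer(num_resolutions)
  if (is.na(num_resolutions) || num_resolutions < 1L)
    vk_stop("usage", "num_resolutions must be a positive integer")
  downsample_factor <- as.integer(downsample_factor)
  if (is.na(downsample_factor) || downsample_factor < 1L)
    vk_stop("usage", "downsample_factor must be a positive integer")
  structure(
    list(extents = extents, voxel_size = voxel_size, unit = unit,
         num_resolutions = num_resolutions,
         downsample_factor = downsample_factor,
         isotropic = isTRUE(isotropic)),
    class = "vk_frame"
  )
}

#' @export
print.vk_frame <- function(x, ...) {
  cat(sprintf("<vk_frame> extents %s, voxel %s %s, %d resolution level(s)\n",
              paste(x$extents, collapse = "x"),
              paste(format(x$voxel_size), collapse = "x"), x$unit,
              x$num_resolutions))
  invisible(x)
}

#' Extents of a frame at a resolution level
#'
#' Downsampled axes shrink as `ceiling(extent / factor^res)`.
#'
#' @param frame A [coordinate_frame()].
#' @param resolution Resolution level (0-based).
#' @return Integer vector of length 3 (X, Y, Z).
#' @export
extents_at <- function(frame, resolution = 0L) {
  check_resolution(frame, resolution)
  f <- frame$downsample_factor^resolution
  down <- c(TRUE, TRUE, frame$isotropic)
  as.integer(ifelse(down, ceiling(frame$extents / f), frame$extents))
}

#' Physical voxel size at a resolution level
#' @inheritParams extents_at
#' @return Numeric vector of length 3, in the frame's unit.
#' @export
voxel_size_at <- function(frame, resolution = 0L) {
  check_resolution(frame, resolution)
  f <- frame$downsample_factor^resolution
  down <- c(TRUE, TRUE, frame$isotropic)
  ifelse(down, frame$voxel_size * f, frame$voxel_size)
}

check_resolution <- function(frame, resolution) {
  resolution <- as.integer(resolution)
  if (is.na(resolution) || resolution < 0L || resolution >= frame$num_resolutions)
    vk_stop("resolution", "resolution %s out of range [0, %d)",
            as.character(resolution), frame$num_resolutions)
  invisible(resolution)
}

frame_to_list <- function(frame) {
  list(extents = frame$extents, voxel_size = frame$voxel_size,
       unit = frame$unit, num_resolutions = frame$num_resolutions,
       downsample_factor = frame$downsample_factor,
       isotropic = frame$isotropic)
}

frame_from_list <- function(x) {
  coordinate_frame(unlist(x$extents), unlist(x$voxel_size),
                   unit = x$unit %||% "nm",
                   num_resolutions = x$num_resolutions %||% 1L,
                   downsample_factor = x$downsample_factor %||% 2L,
                   isotropic = isTRUE(x$isotropic))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
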