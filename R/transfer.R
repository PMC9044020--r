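#' Remote-to-remote subvolume transfer
#'
#' The headline interoperability use case: copy a box of voxels from one
#' remote into another (possibly at an offset), streaming block-at-a-time
#' along the *destination's* chunk grid so writes are chunk-aligned and at
#' most `workers` blocks are resident.  Dtypes must be identical — transfers
#' never cast — and the dtype check happens before any write.
#'
#' @param source,destination Remotes (source readable, destination
#'   writable).
#' @param src_resource,dst_resource Resources (or URIs) on each side.
#' @param box A `vk_request` naming the source box.
#' @param offset Integer XYZ shift applied to the box on the destination.
#' @param resolution Resolution level on both sides.
#' @return A `vk_transfer_job`.
#' @examples
#' src <- memory_remote(); dst <- memory_remote()
#' fr <- coordinate_frame(c(64, 64, 16))
#' ch <- channel_resource("c", "e", "img", frame = fr)
#' create_resource(src, ch); create_resource(dst, ch)
#' post_cutout(src, cutout_request(ch, c(0, 64), c(0, 64), c(0, 16)),
#'             as.array(make_ramp_volume(c(64, 64, 16))))
#' job <- transfer_job(src, ch, dst, ch,
#'                     cutout_request(ch, c(0, 64), c(0, 64), c(0, 16)))
#' rep <- transfer_subvolume(job)
#' verify_transfer(job)$ok
#' @export
transfer_job <- function(source, src_resource, destination, dst_resource,
                         box, offset = c(0L, 0L, 0L), resolution = 0L) {
  offset <- as.integer(offset)
  if (length(offset) != 3L || anyNA(offset))
    vk_stop("usage", "offset must be three integers")
  structure(list(source = source, src_resource = src_resource,
                 destination = destination, dst_resource = dst_resource,
                 box = box, offset = offset,
                 resolution = as.integer(resolution)),
            class = "vk_transfer_job")
}

# destination-side request mirroring `box` shifted by the job offset
dst_request <- function(job, dst_res) {
  cutout_request(dst_res,
                 job$box$x + job$offset[1],
                 job$box$y + job$offset[2],
                 job$box$z + job$offset[3],
                 job$resolution)
}

# the block plan a transfer streams over: destination chunks over the
# destination box
transfer_plan <- function(job) {
  src_meta <- get_metadata(job$source, job$src_resource)
  dst_meta <- get_metadata(job$destination, job$dst_resource)
  if (src_meta$dtype != dst_meta$dtype)
    vk_stop("dtype", "source is %s but destination is %s; transfers never cast",
            src_meta$dtype, dst_meta$dtype)
  validate_request(job$box, src_meta$frame)
  dreq <- validate_request(dst_request(job, dst_meta$resource), dst_meta$frame)
  list(plan = decompose(dreq, dst_meta$chunks),
       src_meta = src_meta, dst_meta = dst_meta, dreq = dreq)
}

#' Execute a transfer job
#'
#' Copies every block of the job's chunk plan.  Per-block failures are
#' recorded and do not abort the remaining blocks; completed blocks stay
#' written, so re-running the same job is idempotent and completes a
#' partial transfer.
#'
#' @param job A [transfer_job()].
#' @param workers Parallel fetchers passed to source reads.
#' @return A `vk_transfer_report`: `blocks_total`, `blocks_done`,
#'   `bytes_moved`, `failed` (chunk keys).
#' @export
transfer_subvolume <- function(job, workers = 1L) {
  tp <- transfer_plan(job)
  plan <- tp$plan
  bpv <- dtype_bytes(tp$src_meta$dtype)
  done <- 0L; bytes <- 0; failed <- character(0)
  for (r in seq_len(nrow(plan))) {
    key <- plan$key[r]
    ok <- tryCatch({
      # destination-side block box -> source-side box via the inverse offset
      sreq <- cutout_request(tp$src_meta$resource,
                             c(plan$gx0[r], plan$gx1[r]) - job$offset[1],
                             c(plan$gy0[r], plan$gy1[r]) - job$offset[2],
                             c(plan$gz0[r], plan$gz1[r]) - job$offset[3],
                             job$resolution)
      block <- get_cutout(job$source, sreq, workers = workers)
      dreq <- cutout_request(tp$dst_meta$resource,
                             c(plan$gx0[r], plan$gx1[r]),
                             c(plan$gy0[r], plan$gy1[r]),
                             c(plan$gz0[r], plan$gz1[r]),
                             job$resolution)
      post_cutout(job$destination, dreq, as.array(block))
      bytes <- bytes + prod(request_shape(dreq)) * bpv
      TRUE
    }, error = function(e) FALSE)
    if (ok) done <- done + 1L else failed <- c(failed, key)
  }
  structure(list(blocks_total = nrow(plan), blocks_done = done,
                 bytes_moved = bytes, failed = failed),
            class = "vk_transfer_report")
}

#' @export
print.vk_transfer_report <- function(x, ...) {
  cat(sprintf("<vk_transfer_report> %d/%d blocks, %s bytes moved%s\n",
              x$blocks_done, x$blocks_total, format(x$bytes_moved, big.mark = ","),
              if (length(x$failed)) sprintf(", %d FAILED", length(x$failed)) else ""))
  invisible(x)
}

#' Verify a completed transfer
#'
#' Re-reads a deterministic seeded sample of the job's blocks from both
#' sides and compares them voxel for voxel; `sample_fraction = 1` compares
#' every block.
#'
#' @param job A completed [transfer_job()].
#' @param sample_fraction Fraction of blocks to compare, in `(0, 1]`.
#' @param seed Seed for the block sample.
#' @return A list: `ok` (logical), `mismatches` (chunk keys), `checked`.
#' @export
verify_transfer <- function(job, sample_fraction = 1, seed = 1L) {
  if (!(sample_fraction > 0 && sample_fraction <= 1))
    vk_stop("usage", "sample_fraction must be in (0, 1]")
  tp <- transfer_plan(job)
  plan <- tp$plan
  n <- nrow(plan)
  rows <- if (sample_fraction >= 1) seq_len(n) else {
    local_rng(seed)
    sort(sample.int(n, max(1L, ceiling(sample_fraction * n))))
  }
  mismatches <- character(0)
  for (r in rows) {
    sreq <- cutout_request(tp$src_meta$resource,
                           c(plan$gx0[r], plan$gx1[r]) - job$offset[1],
                           c(plan$gy0[r], plan$gy1[r]) - job$offset[2],
                           c(plan$gz0[r], plan$gz1[r]) - job$offset[3],
                           job$resolution)
    dreq <- cutout_request(tp$dst_meta$resource,
                           c(plan$gx0[r], plan$gx1[r]),
                           c(plan$gy0[r], plan$gy1[r]),
                           c(plan$gz0[r], plan$gz1[r]),
                           job$resolution)
    a <- as.array(get_cutout(job$source, sreq))
    b <- as.array(get_cutout(job$destination, dreq))
    if (!all(a == b))
      mismatches <- c(mismatches, plan$key[r])
  }
  list(ok = length(mismatches) == 0L, mismatches = mismatches,
       checked = length(rows))
}
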