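#' Image stack container
#'
#' A `slim_stack` holds time-ordered frames (numeric matrices, counts) with
#' per-page channel labels and within-channel frame indices, plus the pixel
#' size and within-channel frame interval. Under alternating two-colour
#' excitation the pages interleave green/red but each channel's own frames
#' remain `frame_ms` apart.
#'
#' @param frames list of numeric matrices, all the same size.
#' @param channel character vector, one label per page.
#' @param frame integer within-channel frame index (0-based), one per page.
#' @param pixel_nm pixel size in nm.
#' @param frame_ms within-channel frame interval in ms.
#' @return a `slim_stack`.
#' @export
slim_stack <- function(frames, channel, frame = NULL, pixel_nm = 80, frame_ms = 5) {
  abort_if(length(frames) != length(channel), "one channel label per page required")
  if (is.null(frame)) {
    frame <- stats::ave(seq_along(channel), channel, FUN = seq_along) - 1L
  }
  structure(list(frames = frames, channel = channel, frame = as.integer(frame),
                 pixel_nm = pixel_nm, frame_ms = frame_ms),
            class = "slim_stack")
}

#' @export
print.slim_stack <- function(x, ...) {
  d <- if (length(x$frames)) dim(x$frames[[1]]) else c(0, 0)
  cat(sprintf("<slim_stack> %d pages (%s), %dx%d px, %g nm/px, %g ms/frame\n",
              length(x$frames),
              paste(sprintf("%s: %d", names(table(x$channel)),
                            as.integer(table(x$channel))), collapse = ", "),
              d[2], d[1], x$pixel_nm, x$frame_ms))
  invisible(x)
}

#' Extract one channel from a stack
#'
#' @param stack a [slim_stack()].
#' @param channel channel label to keep.
#' @return a `slim_stack` with only that channel's pages.
#' @export
get_channel <- function(stack, channel) {
  keep <- stack$channel == channel
  slim_stack(stack$frames[keep], stack$channel[keep], stack$frame[keep],
             stack$pixel_nm, stack$frame_ms)
}

#' Write a stack as a 16-bit multi-page TIFF
#'
#' Pages are written in stack order (interleaved channels stay interleaved);
#' values are clipped to the 16-bit range and quantized to integers.
#'
#' @param stack a [slim_stack()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  mx <- 65535
  pages <- lapply(stack$frames, function(m) pmin(pmax(round(m), 0), mx) / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' Read a multi-page TIFF and de-interleave channels
#'
#' With `interleave = c("green", "red")` odd pages (1st, 3rd, ...) are
#' labelled green and even pages red, emulating alternating-laser
#' acquisition; the page count must then be even. A single label loads all
#' pages into one channel.
#'
#' @param path TIFF file.
#' @param interleave channel labels cycled over pages.
#' @param pixel_nm,frame_ms acquisition metadata to attach.
#' @return a [slim_stack()] (counts on the original 16-bit scale).
#' @export
read_stack <- function(path, interleave = c("green", "red"),
                       pixel_nm = 80, frame_ms = 5) {
  abort_if(!file.exists(path), sprintf("no such TIFF: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (is.matrix(pages)) pages <- list(pages)
  n <- length(pages)
  abort_if(n == 0, sprintf("%s contains no pages", path))
  abort_if(length(interleave) > 1 && n %% length(interleave) != 0,
           sprintf("%s has %d pages, not a multiple of %d channels",
                   path, n, length(interleave)))
  frames <- lapply(pages, function(p) round(p * 65535))
  channel <- rep(interleave, length.out = n)
  slim_stack(frames, channel, pixel_nm = pixel_nm, frame_ms = frame_ms)
}
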