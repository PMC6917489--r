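#' Calibrated image time-lapse container
#'
#' A `frame_stack` couples a `[frame, row, col]` pixel array with its physical
#' calibration: the pixel edge length in nanometres and, for time-lapses, the
#' frame interval in seconds. All downstream operations that convert between
#' physical units (nm, s, um^2) and pixels/frames read the calibration from
#' this container.
#'
#' @param pixels numeric array `[frame, row, col]`, or a matrix for a single
#'   frame (promoted to one frame).
#' @param pixel_size_nm length of one pixel edge in nanometres (> 0).
#' @param frame_interval_s time between frames in seconds (> 0), or `NA` for
#'   single frames / fixed samples.
#' @param channel_name free-text channel label (e.g. `"Lifeact-GFP"`, `"DiI"`).
#' @return An object of class `frame_stack` with fields `pixels`,
#'   `pixel_size_nm`, `frame_interval_s`, `channel_name`.
#' @examples
#' fs <- frame_stack(array(0, c(3, 16, 16)), pixel_size_nm = 100,
#'                   frame_interval_s = 0.1)
#' n_frames(fs)
#' @export
frame_stack <- function(pixels, pixel_size_nm, frame_interval_s = NA_real_,
                        channel_name = "") {
  if (is.matrix(pixels)) {
    pixels <- array(pixels, c(1L, nrow(pixels), ncol(pixels)))
  }
  if (!is.array(pixels) || length(dim(pixels)) != 3L) {
    stop("`pixels` must be a [frame, row, col] array or a matrix")
  }
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0) {
    stop("`pixel_size_nm` must be a single positive number")
  }
  if (!is.na(frame_interval_s) && frame_interval_s <= 0) {
    stop("`frame_interval_s` must be positive (or NA for single frames)")
  }
  if (any(!is.finite(pixels))) stop("`pixels` contains non-finite values")
  storage.mode(pixels) <- "double"
  structure(
    list(pixels = pixels, pixel_size_nm = as.numeric(pixel_size_nm),
         frame_interval_s = as.numeric(frame_interval_s),
         channel_name = channel_name),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<frame_stack> %d frame(s) of %d x %d px | %.1f nm/px | dt = %s s | %s\n",
    d[1], d[2], d[3], x$pixel_size_nm,
    ifelse(is.na(x$frame_interval_s), "NA", format(x$frame_interval_s)),
    ifelse(nzchar(x$channel_name), x$channel_name, "(unnamed channel)")))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack a [frame_stack].
#' @return integer frame count.
#' @export
n_frames <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  dim(stack$pixels)[1]
}

#' Extract one frame as a matrix
#' @param stack a [frame_stack].
#' @param frame 1-based frame index.
#' @return numeric matrix `[row, col]`.
#' @export
get_frame <- function(stack, frame) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$pixels)
  if (frame < 1L || frame > d[1]) stop("frame index out of range")
  matrix(stack$pixels[frame, , ], d[2], d[3])
}

#' Read a TIFF image or time-lapse into a calibrated stack
#'
#' Reads single- or multi-page TIFFs (8/16-bit integer, bit-exact; or 32-bit
#' float, native values). All pages must share dimensions. Multi-sample
#' (RGB) pages are not supported; split channels before import.
#'
#' @param path path to a TIFF file.
#' @inheritParams frame_stack
#' @return a [frame_stack] with frames in file order.
#' @export
read_stack <- function(path, pixel_size_nm, frame_interval_s = NA_real_,
                       channel_name = "") {
  if (!file.exists(path)) stop("cannot read TIFF: ", path)
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE),
    error = function(e) tiff::readTIFF(path, all = TRUE)
  )
  if (!length(pages)) stop("no pages in TIFF: ", path)
  dims <- lapply(pages, dim)
  if (any(vapply(dims, length, 1L) != 2L)) {
    stop("multi-sample (e.g. RGB) TIFF pages are not supported: ", path)
  }
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L) {
    stop("TIFF pages have inconsistent dimensions: ", path)
  }
  px <- aperm(simplify2array(pages), c(3L, 1L, 2L))
  frame_stack(px, pixel_size_nm, frame_interval_s, channel_name)
}

#' Write a stack as a multi-page 16-bit TIFF
#'
#' Values are rounded to integers and stored as 16-bit unsigned samples
#' (camera digital-number semantics). Integer-valued stacks in `[0, 65535]`
#' round-trip bit-exactly through [read_stack()].
#'
#' @param stack a [frame_stack]; values must lie in `[0, 65535]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  px <- stack$pixels
  if (min(px) < 0 || max(px) > 65535) {
    stop("write_stack stores 16-bit samples; values must lie in [0, 65535]")
  }
  d <- dim(px)
  pages <- lapply(seq_len(d[1]), function(t) {
    round(matrix(px[t, , ], d[2], d[3])) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  compression = "none", reduce = FALSE)
  invisible(path)
}
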