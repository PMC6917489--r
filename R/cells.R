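#' Cell (synapse) footprint mask
#'
#' @param mask logical matrix marking the cell footprint.
#' @param pixel_size_nm pixel edge length, nm.
#' @param cell_id integer label.
#' @return object of class `cell_mask` with fields `mask`, `cell_id`,
#'   `pixel_size_nm`, `area_um2` (pixel count times `(pixel_size_nm/1000)^2`).
#' @export
cell_mask <- function(mask, pixel_size_nm, cell_id = 1L) {
  stopifnot(is.matrix(mask))
  mask <- mask != 0
  structure(
    list(mask = mask, cell_id = as.integer(cell_id),
         pixel_size_nm = pixel_size_nm,
         area_um2 = sum(mask) * (pixel_size_nm / 1000)^2),
    class = "cell_mask")
}

#' @export
print.cell_mask <- function(x, ...) {
  cat(sprintf("<cell_mask> id %d | %d px | %.2f um^2\n",
              x$cell_id, sum(x$mask), x$area_um2))
  invisible(x)
}

#' Segment cells from actin intensity
#'
#' Cells are identified on the first frame by a global automatic (Otsu)
#' threshold of the median-smoothed actin image, followed by hole filling and
#' 8-connected labeling. Regions smaller than `min_cell_area_um2` are
#' dropped; no other exclusion is applied. The mask is computed once and held
#' fixed over the movie (cells are spread and stationary on the timescale
#' analysed here).
#'
#' @param stack a [frame_stack] of the actin channel.
#' @param min_cell_area_um2 minimum region area, um^2.
#' @return list of [cell_mask] objects (possibly empty), ordered by raster
#'   position and numbered from 1. Constant images yield an empty list.
#' @export
segment_cells <- function(stack, min_cell_area_um2 = 20) {
  stopifnot(inherits(stack, "frame_stack"))
  f <- get_frame(stack, 1L)
  rng <- range(f)
  if (diff(rng) <= 0) return(list())
  norm <- (f - rng[1]) / diff(rng)
  sm <- EBImage::medianFilter(norm, size = 2L)
  thr <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1), levels = 256L)
  bin <- sm > thr
  bin <- EBImage::fillHull(bin)
  labels <- label_components(bin, 8L)
  if (!max(labels)) return(list())
  min_px <- min_cell_area_um2 / (stack$pixel_size_nm / 1000)^2
  areas <- tabulate(labels[labels > 0L])
  keep <- which(areas >= min_px)
  out <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    out[[i]] <- cell_mask(labels == keep[i], stack$pixel_size_nm, cell_id = i)
  }
  out
}
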