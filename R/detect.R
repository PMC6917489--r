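#' Threshold a response map relative to the cell's mean actin intensity
#'
#' Retains pixels inside the cell whose response is at least `fraction`
#' times the mean *raw* actin intensity over the cell mask. Referencing the
#' raw frame (rather than the response) is well defined for both spot and
#' ridge responses; because all kernels are unit-sum the two references
#' coincide on uniform images.
#'
#' @param response a [response_map].
#' @param frame the raw actin frame the response was computed from.
#' @param cell a [cell_mask].
#' @param fraction positive threshold fraction.
#' @return logical matrix (subset of the cell mask).
#' @export
threshold_relative <- function(response, frame, cell, fraction) {
  stopifnot(inherits(response, "response_map"), inherits(cell, "cell_mask"),
            is.matrix(frame), fraction > 0)
  if (!any(cell$mask)) stop("empty cell mask")
  thr <- fraction * mean(frame[cell$mask])
  cell$mask & (response$values >= thr)
}

#' Per-frame set of labeled actin foci
#'
#' @param frame_index 1-based frame index.
#' @param labels integer label matrix (0 = background).
#' @param table tibble with one row per focus: `focus_id`, `row`, `col`
#'   (intensity-weighted centroid), `area_px`, `elongation`.
#' @param cell_id owning cell label.
#' @return object of class `foci_set`.
#' @export
foci_set <- function(frame_index, labels, table, cell_id = 1L) {
  structure(list(frame_index = as.integer(frame_index), labels = labels,
                 table = table, cell_id = as.integer(cell_id)),
            class = "foci_set")
}

#' @export
print.foci_set <- function(x, ...) {
  cat(sprintf("<foci_set> frame %d | cell %d | %d foci\n",
              x$frame_index, x$cell_id, nrow(x$table)))
  invisible(x)
}

#' Per-frame binary fiber mask
#' @param frame_index 1-based frame index.
#' @param mask logical matrix of fiber pixels.
#' @param cell_id owning cell label.
#' @return object of class `fiber_mask`.
#' @export
fiber_mask <- function(frame_index, mask, cell_id = 1L) {
  structure(list(frame_index = as.integer(frame_index), mask = mask != 0,
                 cell_id = as.integer(cell_id)),
            class = "fiber_mask")
}

#' Detect actin foci by spot-vs-ridge competition
#'
#' Candidate foci pixels are those of the thresholded foci mask where the
#' spot response strictly exceeds the ridge response (ties go to the fiber
#' class). Candidates are labeled with 8-connectivity, and components that
#' are small (`area < min_focus_area_px`) or highly elongated
#' (`elongation > max_elongation`, major/minor axis ratio of the
#' second-moment ellipse) are removed. Centroids are weighted by the spot
#' response.
#'
#' @param foci_mask logical matrix from [threshold_relative()] of the foci
#'   response.
#' @param foci_resp,fiber_resp [response_map]s of matching shape.
#' @param cfg a [pipeline_config()] (uses `min_focus_area_px`,
#'   `max_elongation`).
#' @param frame_index,cell_id bookkeeping labels carried into the result.
#' @return a [foci_set]; may contain zero foci.
#' @export
detect_foci <- function(foci_mask, foci_resp, fiber_resp, cfg,
                        frame_index = 1L, cell_id = 1L) {
  stopifnot(inherits(foci_resp, "response_map"),
            inherits(fiber_resp, "response_map"),
            identical(dim(foci_mask), dim(foci_resp$values)),
            identical(dim(foci_mask), dim(fiber_resp$values)))
  cand <- foci_mask & (foci_resp$values > fiber_resp$values)
  labels <- label_components(cand, 8L)
  st <- component_stats(labels, weights = foci_resp$values)
  keep <- st$area_px >= cfg$min_focus_area_px &
    st$elongation <= cfg$max_elongation
  st <- st[keep, , drop = FALSE]
  relab <- matrix(0L, nrow(labels), ncol(labels))
  if (nrow(st)) {
    map <- integer(max(labels))
    map[st$label] <- seq_len(nrow(st))
    sel <- labels > 0L
    relab[sel] <- map[labels[sel]]
  }
  tab <- tibble(focus_id = seq_len(nrow(st)), row = st$row, col = st$col,
                area_px = st$area_px, elongation = st$elongation)
  foci_set(frame_index, relab, tab, cell_id)
}

#' Detect actin fibers
#'
#' Thresholds the ridge response at `fraction` times the cell's mean actin
#' intensity, then removes all pixels belonging to detected foci, so foci
#' and fibers are disjoint by construction.
#'
#' @param fiber_resp a [response_map] of kind `"fiber"`.
#' @param frame raw actin frame.
#' @param cell a [cell_mask].
#' @param foci the frame's [foci_set].
#' @param fraction fiber threshold fraction.
#' @return a [fiber_mask].
#' @export
detect_fibers <- function(fiber_resp, frame, cell, foci, fraction) {
  stopifnot(inherits(foci, "foci_set"))
  m <- threshold_relative(fiber_resp, frame, cell, fraction)
  m[foci$labels > 0L] <- FALSE
  fiber_mask(foci$frame_index, m, cell$cell_id)
}

#' Segment foci and fibers in every frame of a movie
#'
#' Convenience wrapper running [enhance_foci()], [enhance_fibers()],
#' [threshold_relative()], [detect_foci()] and [detect_fibers()] per frame
#' for one cell.
#'
#' @param stack actin [frame_stack].
#' @param cell a [cell_mask].
#' @param cfg a [pipeline_config()].
#' @return list with `foci_by_frame` (list of [foci_set]) and
#'   `fibers_by_frame` (list of [fiber_mask]).
#' @export
segment_stack <- function(stack, cell, cfg) {
  stopifnot(inherits(stack, "frame_stack"), inherits(cell, "cell_mask"),
            inherits(cfg, "pipeline_config"))
  nt <- n_frames(stack)
  foci_by_frame <- vector("list", nt)
  fibers_by_frame <- vector("list", nt)
  for (t in seq_len(nt)) {
    fr <- get_frame(stack, t)
    fo <- enhance_foci(fr, cfg$foci_scale_nm, stack$pixel_size_nm)
    fi <- enhance_fibers(fr, cfg$fiber_scale_nm, stack$pixel_size_nm,
                         cfg$n_orientations)
    fm <- threshold_relative(fo, fr, cell, cfg$foci_threshold_fraction)
    foci <- detect_foci(fm, fo, fi, cfg, frame_index = t,
                        cell_id = cell$cell_id)
    fibers <- detect_fibers(fi, fr, cell, foci, cfg$fiber_threshold_fraction)
    # restrict foci to the cell footprint (thresholding already does)
    foci_by_frame[[t]] <- foci
    fibers_by_frame[[t]] <- fibers
  }
  list(foci_by_frame = foci_by_frame, fibers_by_frame = fibers_by_frame)
}

#' Tabulate foci detections over frames
#'
#' @param foci_by_frame list of [foci_set].
#' @return tibble with `frame`, `cell_id`, `focus_id`, `row`, `col`,
#'   `area_px`.
#' @export
foci_table <- function(foci_by_frame) {
  rows <- lapply(foci_by_frame, function(fs) {
    if (!nrow(fs$table)) return(NULL)
    tibble(frame = fs$frame_index, cell_id = fs$cell_id,
           focus_id = fs$table$focus_id, row = fs$table$row,
           col = fs$table$col, area_px = fs$table$area_px)
  })
  out <- bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble(frame = integer(), cell_id = integer(),
                  focus_id = integer(), row = numeric(), col = numeric(),
                  area_px = integer())
  }
  out
}
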