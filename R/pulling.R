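#' Detect bright DiI membrane structures
#'
#' Membrane deformations appear as local increases of DiI fluorescence.
#' Each frame is band-pass filtered with a difference of Gaussians (core
#' FWHM `cfg$dii_scale_nm`, surround twice that) and strict 8-neighbour
#' local maxima inside the cell footprint are kept if the band-pass value
#' exceeds `cfg$dii_threshold_k` robust (MAD) SDs of the in-cell response.
#' Centers are refined to the response-weighted centroid of the 3x3
#' neighbourhood.
#'
#' @param dii_stack DiI [frame_stack], registered to the actin channel.
#' @param cell a [cell_mask].
#' @param cfg a [pipeline_config()].
#' @return tibble of structure centers: `frame`, `row`, `col`, `response`.
#' @export
detect_membrane_structures <- function(dii_stack, cell, cfg) {
  stopifnot(inherits(dii_stack, "frame_stack"), inherits(cell, "cell_mask"))
  sigma <- cfg$dii_scale_nm / (2.355 * dii_stack$pixel_size_nm)
  k1 <- gaussian_kernel(sigma)
  k2 <- gaussian_kernel(2 * sigma)
  # the cell edge itself is a strong band-pass feature; search for maxima
  # only beyond the surround kernel's reach from the boundary
  rim <- ceiling(2 * 2 * sigma)
  core_mask <- EBImage::distmap(cell$mask * 1) > rim
  nt <- n_frames(dii_stack)
  rows <- vector("list", nt)
  for (t in seq_len(nt)) {
    fr <- get_frame(dii_stack, t)
    dog <- convolve_reflect(fr, k1) - convolve_reflect(fr, k2)
    ref_px <- if (any(core_mask)) core_mask else cell$mask
    sd_hat <- mad(dog[ref_px])
    thr <- cfg$dii_threshold_k * sd_hat
    nr <- nrow(dog); nc <- ncol(dog)
    # strict local maximum over the 8-neighbourhood (border excluded)
    core <- dog[2:(nr - 1), 2:(nc - 1)]
    is_max <- core > dog[1:(nr - 2), 2:(nc - 1)] &
      core > dog[3:nr, 2:(nc - 1)] &
      core > dog[2:(nr - 1), 1:(nc - 2)] &
      core > dog[2:(nr - 1), 3:nc] &
      core > dog[1:(nr - 2), 1:(nc - 2)] &
      core > dog[1:(nr - 2), 3:nc] &
      core > dog[3:nr, 1:(nc - 2)] &
      core > dog[3:nr, 3:nc] &
      core >= thr &
      core_mask[2:(nr - 1), 2:(nc - 1)]
    pk <- which(is_max, arr.ind = TRUE)
    if (!nrow(pk)) next
    pr <- pk[, 1] + 1L
    pc <- pk[, 2] + 1L
    # 3x3 response-weighted sub-pixel refinement
    ref_r <- ref_c <- numeric(length(pr))
    for (q in seq_along(pr)) {
      rr <- (pr[q] - 1L):(pr[q] + 1L)
      cc <- (pc[q] - 1L):(pc[q] + 1L)
      w <- pmax(dog[rr, cc], 0)
      if (sum(w) == 0) w[] <- 1
      ref_r[q] <- sum(outer(rr, rep(1, 3)) * w) / sum(w)
      ref_c[q] <- sum(outer(rep(1, 3), cc) * w) / sum(w)
    }
    rows[[t]] <- tibble(frame = t, row = ref_r, col = ref_c,
                        response = dog[cbind(pr, pc)])
  }
  out <- bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble(frame = integer(), row = numeric(), col = numeric(),
                  response = numeric())
  }
  out
}

#' Track membrane structures and keep dynamic ones
#'
#' Structures are linked with the same frame-to-frame linker as actin foci.
#' To exclude preexisting membrane structures not generated by the cell, an
#' event is retained only if it *appeared* (its track starts after the first
#' movie frame) or *moved* (net start-to-end motion of at least
#' `motion_threshold_px`).
#'
#' @param series structure-center tibble from
#'   [detect_membrane_structures()].
#' @param motion_threshold_px net-motion threshold, px.
#' @param link_max_dist_nm tracking gate, nm.
#' @param pixel_size_nm pixel edge length, nm.
#' @return list with `events` (one row per retained dynamic event:
#'   `event_id`, `start_frame`, `end_frame`, `n_frames`, `appeared`,
#'   `net_motion_px`) and `points` (their per-frame centers: `event_id`,
#'   `frame`, `row`, `col`).
#' @export
track_and_filter_dynamic <- function(series, motion_threshold_px,
                                     link_max_dist_nm, pixel_size_nm) {
  stopifnot(motion_threshold_px >= 0)
  tracks <- link_foci(series, link_max_dist_nm, pixel_size_nm)
  if (!nrow(tracks)) {
    return(list(
      events = tibble(event_id = integer(), start_frame = integer(),
                      end_frame = integer(), n_frames = integer(),
                      appeared = logical(), net_motion_px = numeric()),
      points = tibble(event_id = integer(), frame = integer(),
                      row = numeric(), col = numeric())))
  }
  st <- tracks |>
    group_by(.data$track_id) |>
    arrange(.data$frame, .by_group = TRUE) |>
    summarise(start_frame = min(.data$frame), end_frame = max(.data$frame),
              n_frames = n(),
              net_motion_px = sqrt((.data$row[n()] - .data$row[1])^2 +
                                   (.data$col[n()] - .data$col[1])^2),
              .groups = "drop") |>
    mutate(appeared = .data$start_frame > 1L,
           dynamic = .data$appeared |
             .data$net_motion_px >= motion_threshold_px)
  keep <- st[st$dynamic, ]
  keep$event_id <- seq_len(nrow(keep))
  pts <- tracks[tracks$track_id %in% keep$track_id, ]
  pts$event_id <- keep$event_id[match(pts$track_id, keep$track_id)]
  list(
    events = keep[, c("event_id", "start_frame", "end_frame", "n_frames",
                      "appeared", "net_motion_px")],
    points = arrange(pts[, c("event_id", "frame", "row", "col")],
                     .data$event_id, .data$frame))
}

#' Associate pulling events with actin structures
#'
#' An event is associated with foci if its center lies on a detected focus
#' pixel in any frame of its lifetime, with fibers likewise; `both` if both
#' occur, `none` otherwise.
#'
#' @param events list from [track_and_filter_dynamic()].
#' @param foci_by_frame list of [foci_set] indexed by frame.
#' @param fibers_by_frame list of [fiber_mask] indexed by frame.
#' @return `events` with `on_foci`, `on_fibers` and `association`
#'   (`"foci"`, `"fibers"`, `"both"`, `"none"`) added to `$events`.
#' @export
associate_events <- function(events, foci_by_frame, fibers_by_frame) {
  ev <- events$events
  pts <- events$points
  on_foci <- on_fibers <- rep(FALSE, nrow(ev))
  if (nrow(pts)) {
    for (q in seq_len(nrow(pts))) {
      t <- pts$frame[q]
      if (t < 1L || t > length(foci_by_frame)) next
      fl <- foci_by_frame[[t]]$labels
      fm <- fibers_by_frame[[t]]$mask
      pr <- min(max(round(pts$row[q]), 1L), nrow(fl))
      pc <- min(max(round(pts$col[q]), 1L), ncol(fl))
      e <- match(pts$event_id[q], ev$event_id)
      if (fl[pr, pc] > 0L) on_foci[e] <- TRUE
      if (fm[pr, pc]) on_fibers[e] <- TRUE
    }
  }
  ev$on_foci <- on_foci
  ev$on_fibers <- on_fibers
  ev$association <- ifelse(on_foci & on_fibers, "both",
                           ifelse(on_foci, "foci",
                                  ifelse(on_fibers, "fibers", "none")))
  events$events <- ev
  events
}

#' Summarize membrane-pulling activity for one cell
#'
#' Event density is the mean over frames of active dynamic events per um^2
#' of synapse area. Association percentages count an event in each category
#' it touches (`both` contributes to foci and fibers, and is also reported
#' separately). Area-normalized rates divide the number of associated events
#' by the mean area (um^2) the structure covers per frame, the construction
#' used to compare the pulling efficiency of foci and fibers.
#'
#' @param events associated events list (see [associate_events()]).
#' @param cell a [cell_mask].
#' @param foci_by_frame list of [foci_set].
#' @param fibers_by_frame list of [fiber_mask].
#' @return one-row tibble: `cell_id`, `n_events`,
#'   `events_per_um2_per_frame`, `pct_events_foci`, `pct_events_fibers`,
#'   `pct_events_both`, `pct_events_none`, `rate_per_foci_area`,
#'   `rate_per_fiber_area` (events per um^2 of structure; `NaN` with a
#'   warning when a structure covers zero area).
#' @export
summarize_pulling <- function(events, cell, foci_by_frame, fibers_by_frame) {
  stopifnot(inherits(cell, "cell_mask"))
  ev <- events$events
  if (is.null(ev$association)) stop("run associate_events() first")
  n_frames_movie <- length(foci_by_frame)
  px_um2 <- (cell$pixel_size_nm / 1000)^2
  foci_area <- mean(vapply(foci_by_frame,
                           function(f) sum(f$labels > 0L), 0)) * px_um2
  fiber_area <- mean(vapply(fibers_by_frame,
                            function(f) sum(f$mask), 0)) * px_um2
  n_ev <- nrow(ev)
  n_foci <- sum(ev$on_foci)
  n_fib <- sum(ev$on_fibers)
  rate_foci <- if (foci_area > 0) n_foci / foci_area else {
    warning("zero foci area; foci-normalized rate undefined"); NaN
  }
  rate_fib <- if (fiber_area > 0) n_fib / fiber_area else {
    warning("zero fiber area; fiber-normalized rate undefined"); NaN
  }
  tibble(
    cell_id = cell$cell_id,
    n_events = n_ev,
    events_per_um2_per_frame =
      nrow(events$points) / n_frames_movie / cell$area_um2,
    pct_events_foci = if (n_ev) 100 * n_foci / n_ev else NaN,
    pct_events_fibers = if (n_ev) 100 * n_fib / n_ev else NaN,
    pct_events_both = if (n_ev) 100 * mean(ev$association == "both") else NaN,
    pct_events_none = if (n_ev) 100 * mean(ev$association == "none") else NaN,
    rate_per_foci_area = rate_foci,
    rate_per_fiber_area = rate_fib)
}
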