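#' Link per-frame foci into tracks
#'
#' Frame-to-frame linking by optimal one-to-one assignment (shortest
#' augmenting path): between consecutive frames, open track ends are matched
#' to new detections so that, among matchings using only pairs within the
#' distance gate, cardinality is maximal and total centroid displacement is
#' minimal. Unmatched detections start new tracks. There is no gap closing:
#' a focus missing for one frame terminates its track, consistent with the
#' strict two-frame persistence filter applied downstream.
#'
#' @param foci_by_frame list of [foci_set] objects (ordered by frame), or a
#'   data frame of detections with columns `frame`, `row`, `col` (optional
#'   `cell_id`).
#' @param link_max_dist_nm gate: maximum frame-to-frame centroid jump, nm.
#' @param pixel_size_nm pixel edge length, nm.
#' @return tibble of track points: `track_id`, `cell_id`, `frame`, `row`,
#'   `col`. Track ids are assigned in order of track creation.
#' @export
link_foci <- function(foci_by_frame, link_max_dist_nm, pixel_size_nm) {
  stopifnot(link_max_dist_nm > 0, pixel_size_nm > 0)
  det <- if (is.data.frame(foci_by_frame)) {
    d <- as_tibble(foci_by_frame)
    if (!all(c("frame", "row", "col") %in% names(d))) {
      stop("detection table needs columns frame, row, col")
    }
    if (!"cell_id" %in% names(d)) d$cell_id <- 1L
    d[, c("frame", "cell_id", "row", "col")]
  } else {
    foci_table(foci_by_frame)[, c("frame", "cell_id", "row", "col")]
  }
  det <- arrange(det, .data$frame, .data$row, .data$col)
  gate_px <- link_max_dist_nm / pixel_size_nm
  out_track <- integer(nrow(det))
  if (nrow(det)) {
    frames <- sort(unique(det$frame))
    by_frame <- split(seq_len(nrow(det)), det$frame)
    next_id <- 1L
    open_rows <- integer()  # det row index of each open track's last point
    open_ids <- integer()
    for (fi in seq_along(frames)) {
      f <- frames[fi]
      rows <- by_frame[[as.character(f)]]
      contiguous <- fi > 1L && frames[fi - 1L] == f - 1L
      if (!contiguous) { open_rows <- integer(); open_ids <- integer() }
      if (length(open_rows)) {
        a <- cbind(det$row[open_rows], det$col[open_rows])
        b <- cbind(det$row[rows], det$col[rows])
        m <- match_points_gated(a, b, gate_px)
      } else {
        m <- integer()
      }
      new_open_rows <- integer(); new_open_ids <- integer()
      matched_b <- rep(FALSE, length(rows))
      for (k in seq_along(m)) {
        if (!is.na(m[k])) {
          r <- rows[m[k]]
          out_track[r] <- open_ids[k]
          matched_b[m[k]] <- TRUE
          new_open_rows <- c(new_open_rows, r)
          new_open_ids <- c(new_open_ids, open_ids[k])
        }
      }
      for (k in which(!matched_b)) {
        r <- rows[k]
        out_track[r] <- next_id
        new_open_rows <- c(new_open_rows, r)
        new_open_ids <- c(new_open_ids, next_id)
        next_id <- next_id + 1L
      }
      ord <- order(new_open_ids)
      open_rows <- new_open_rows[ord]
      open_ids <- new_open_ids[ord]
    }
  }
  det$track_id <- out_track
  arrange(det[, c("track_id", "cell_id", "frame", "row", "col")],
          .data$track_id, .data$frame)
}

#' Per-track statistics
#'
#' Lifetime of an n-frame track is `n * frame_interval_s`; displacement is
#' the Euclidean start-to-end centroid distance in nm; speed is displacement
#' divided by lifetime.
#'
#' @param tracks track-point tibble from [link_foci()].
#' @param pixel_size_nm pixel edge length, nm.
#' @param frame_interval_s frame interval, s.
#' @return tibble with one row per track: `track_id`, `cell_id`, `n_frames`,
#'   `start_frame`, `end_frame`, `lifetime_s`, `displacement_nm`,
#'   `speed_nm_per_s`.
#' @export
track_stats <- function(tracks, pixel_size_nm, frame_interval_s) {
  stopifnot(pixel_size_nm > 0, frame_interval_s > 0)
  if (!nrow(tracks)) {
    return(tibble(track_id = integer(), cell_id = integer(),
                  n_frames = integer(), start_frame = integer(),
                  end_frame = integer(), lifetime_s = numeric(),
                  displacement_nm = numeric(), speed_nm_per_s = numeric()))
  }
  tracks |>
    group_by(.data$track_id) |>
    arrange(.data$frame, .by_group = TRUE) |>
    summarise(
      cell_id = .data$cell_id[1],
      n_frames = n(),
      start_frame = min(.data$frame),
      end_frame = max(.data$frame),
      displacement_nm = sqrt((.data$row[n()] - .data$row[1])^2 +
                             (.data$col[n()] - .data$col[1])^2) *
        pixel_size_nm,
      .groups = "drop") |>
    mutate(lifetime_s = .data$n_frames * frame_interval_s,
           speed_nm_per_s = .data$displacement_nm / .data$lifetime_s) |>
    (\(d) d[, c("track_id", "cell_id", "n_frames", "start_frame",
                "end_frame", "lifetime_s", "displacement_nm",
                "speed_nm_per_s")])()
}

#' Discard short-lived tracks
#'
#' Removes tracks persisting for fewer than `min_track_frames` frames
#' (default two, the persistence filter applied before all dynamics
#' statistics).
#'
#' @param tracks track-point tibble from [link_foci()].
#' @param min_track_frames minimum number of frames (>= 1).
#' @return filtered track-point tibble.
#' @export
prune_tracks <- function(tracks, min_track_frames = 2L) {
  stopifnot(min_track_frames >= 1L)
  if (!nrow(tracks)) return(tracks)
  tracks |>
    group_by(.data$track_id) |>
    filter(n() >= min_track_frames) |>
    ungroup()
}

#' Per-cell foci dynamics summary
#'
#' Foci density is the mean number of tracked foci per time point,
#' normalized per 10 um^2 of cell area. Lifetime and displacement means are
#' over pruned tracks.
#'
#' @param tracks *pruned* track-point tibble (see [prune_tracks()]).
#' @param cell a [cell_mask] (area must be positive).
#' @param n_movie_frames number of frames in the movie.
#' @param frame_interval_s frame interval, s.
#' @param pixel_size_nm pixel edge length, nm.
#' @return one-row tibble: `cell_id`, `foci_per_10um2`, `mean_lifetime_s`,
#'   `mean_displacement_nm`, `n_tracks`. Means are `NaN` when no tracks.
#' @export
summarize_cell <- function(tracks, cell, n_movie_frames, frame_interval_s,
                           pixel_size_nm) {
  stopifnot(inherits(cell, "cell_mask"), n_movie_frames >= 1)
  if (cell$area_um2 <= 0) stop("cell has zero area")
  st <- track_stats(tracks, pixel_size_nm, frame_interval_s)
  tibble(
    cell_id = cell$cell_id,
    foci_per_10um2 = (nrow(tracks) / n_movie_frames) / cell$area_um2 * 10,
    mean_lifetime_s = if (nrow(st)) mean(st$lifetime_s) else NaN,
    mean_displacement_nm = if (nrow(st)) mean(st$displacement_nm) else NaN,
    n_tracks = nrow(st))
}

#' Survivorship-corrected exponential lifetime estimate
#'
#' Tracked lifetimes are biased by the `min_track_frames` persistence filter
#' and by movie-boundary censoring. For an exponential lifetime with mean
#' `tau`, the frame count N of a focus is geometric with
#' `p = 1 - exp(-dt / tau)`, and the excess `M = N - min_track_frames` of a
#' surviving track is geometric on 0, 1, 2, .... The maximum-likelihood
#' estimate with right censoring (tracks still present in the last movie
#' frame) is `p_hat = deaths / (deaths + sum(M))`; tracks already present in
#' frame 1 enter unchanged by memorylessness. The estimate returned is
#' `tau_hat = -dt / log(1 - p_hat)`.
#'
#' @param stats per-track tibble from [track_stats()] (pruned tracks).
#' @param frame_interval_s frame interval, s.
#' @param min_track_frames persistence filter used upstream.
#' @param n_movie_frames number of frames in the movie (for censoring); `NULL`
#'   treats all track ends as observed deaths.
#' @return estimated mean lifetime in seconds (`NaN` if no deaths observed).
#' @export
estimate_lifetime_mean <- function(stats, frame_interval_s,
                                   min_track_frames = 2L,
                                   n_movie_frames = NULL) {
  stopifnot(frame_interval_s > 0)
  if (!nrow(stats)) return(NaN)
  m_excess <- stats$n_frames - min_track_frames
  if (any(m_excess < 0)) stop("stats contain tracks shorter than the filter")
  deaths <- if (is.null(n_movie_frames)) rep(TRUE, nrow(stats)) else
    stats$end_frame < n_movie_frames
  nd <- sum(deaths)
  if (nd == 0L) return(NaN)
  p_hat <- nd / (nd + sum(m_excess))
  if (p_hat >= 1) return(frame_interval_s * min_track_frames)
  -frame_interval_s / log(1 - p_hat)
}
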