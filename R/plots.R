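#' Plot foci trajectories
#'
#' Draws each track as a path in pixel coordinates, colored by track id,
#' with the y axis flipped to match image orientation.
#'
#' @param tracks track-point tibble from [link_foci()].
#' @return a ggplot object.
#' @export
plot_tracks <- function(tracks) {
  ggplot2::ggplot(tracks,
                  ggplot2::aes(x = .data$col, y = .data$row,
                               group = .data$track_id,
                               colour = factor(.data$track_id))) +
    ggplot2::geom_path(alpha = 0.7, show.legend = FALSE) +
    ggplot2::geom_point(size = 0.4, show.legend = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "col (px)", y = "row (px)",
                  title = "Foci trajectories") +
    ggplot2::theme_minimal()
}

#' Plot the track lifetime distribution
#'
#' Histogram of track lifetimes in seconds with the mean marked, the
#' standard view of focus turnover.
#'
#' @param stats per-track tibble from [track_stats()].
#' @param binwidth_s histogram bin width, s.
#' @return a ggplot object.
#' @export
plot_lifetime_distribution <- function(stats, binwidth_s = 0.5) {
  ggplot2::ggplot(stats, ggplot2::aes(x = .data$lifetime_s)) +
    ggplot2::geom_histogram(binwidth = binwidth_s, boundary = 0,
                            fill = "grey35", colour = "white") +
    ggplot2::geom_vline(xintercept = mean(stats$lifetime_s),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "lifetime (s)", y = "tracks",
                  title = "Focus lifetimes") +
    ggplot2::theme_minimal()
}
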