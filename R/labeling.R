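#' Label connected components of a binary mask
#'
#' Connected-component labeling with 8- (default) or 4-connectivity. Labels
#' are assigned deterministically in raster order of each component's first
#' (lowest linear index) pixel. Implemented over a pixel-adjacency graph so
#' that diagonal contacts join components under 8-connectivity.
#'
#' @param mask logical (or 0/1 numeric) matrix.
#' @param connectivity 8 (queen) or 4 (rook).
#' @return integer matrix of the same shape; 0 = background, components
#'   numbered from 1.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (!length(idx)) return(labels)
  pos <- integer(nr * nc)
  pos[idx] <- seq_along(idx)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) shifts <- c(shifts, list(c(1L, 1L), c(-1L, 1L)))
  edges <- lapply(shifts, function(s) {
    nidx <- idx + s[1] + s[2] * nr
    ok <- rows + s[1] >= 1L & rows + s[1] <= nr & cols + s[2] <= nc
    ok[ok] <- mask[nidx[ok]]
    cbind(pos[idx[ok]], pos[nidx[ok]])
  })
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  labels[idx] <- match(memb, unique(memb))  # raster order of first pixels
  labels
}

#' Shape statistics of labeled components
#'
#' Computes, per label: pixel area, centroid (optionally intensity-weighted),
#' and elongation, defined as the major/minor axis ratio of the component's
#' second-moment ellipse. Second moments use unweighted pixel coordinates
#' with a 1/12 pixel-extent correction per axis, so a single pixel has
#' elongation 1 and a 1-px-wide line of length L has elongation ~ L.
#'
#' @param labels integer label matrix from [label_components()].
#' @param weights optional numeric matrix of the same shape; when given,
#'   centroids are intensity-weighted.
#' @return a tibble with columns `label`, `area_px`, `row`, `col`,
#'   `elongation`.
#' @export
component_stats <- function(labels, weights = NULL) {
  stopifnot(is.matrix(labels))
  idx <- which(labels > 0L)
  if (!length(idx)) {
    return(tibble(label = integer(), area_px = integer(),
                  row = numeric(), col = numeric(), elongation = numeric()))
  }
  lab <- labels[idx]
  nr <- nrow(labels)
  r <- (idx - 1) %% nr + 1
  co <- (idx - 1) %/% nr + 1
  w <- if (is.null(weights)) rep(1, length(idx)) else as.numeric(weights[idx])
  if (any(w < 0)) w <- pmax(w, 0)
  ids <- sort(unique(lab))
  area <- as.vector(rowsum(rep(1L, length(idx)), lab))
  sw <- as.vector(rowsum(w, lab))
  sw[sw == 0] <- NA_real_
  cr <- as.vector(rowsum(w * r, lab)) / sw
  cc <- as.vector(rowsum(w * co, lab)) / sw
  # fall back to unweighted centroid where weights sum to zero
  ur <- as.vector(rowsum(r, lab)) / area
  uc <- as.vector(rowsum(co, lab)) / area
  cr[is.na(cr)] <- ur[is.na(cr)]
  cc[is.na(cc)] <- uc[is.na(cc)]
  # unweighted central second moments + pixel-extent correction
  vrr <- as.vector(rowsum(r * r, lab)) / area - ur^2 + 1 / 12
  vcc <- as.vector(rowsum(co * co, lab)) / area - uc^2 + 1 / 12
  vrc <- as.vector(rowsum(r * co, lab)) / area - ur * uc
  tr <- vrr + vcc
  det_rt <- sqrt(pmax((vrr - vcc)^2 + 4 * vrc^2, 0))
  l1 <- (tr + det_rt) / 2
  l2 <- (tr - det_rt) / 2
  elong <- ifelse(l2 <= 0, Inf, sqrt(l1 / l2))
  tibble(label = ids, area_px = as.integer(area), row = cr, col = cc,
         elongation = elong)
}
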