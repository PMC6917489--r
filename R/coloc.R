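# helpers: coerce the "regions" argument (foci_set / fiber_mask / matrix)
# to an integer label matrix with one label per region.
regions_labels <- function(regions) {
  if (inherits(regions, "foci_set")) return(regions$labels)
  if (inherits(regions, "fiber_mask")) return(label_components(regions$mask))
  if (is.matrix(regions)) {
    if (is.logical(regions) || all(regions %in% c(0, 1))) {
      return(label_components(regions != 0))
    }
    return(matrix(as.integer(regions), nrow(regions), ncol(regions)))
  }
  stop("`regions` must be a foci_set, fiber_mask, or matrix")
}

points_matrix <- function(points) {
  if (is.data.frame(points)) {
    stopifnot(all(c("row", "col") %in% names(points)))
    return(cbind(points$row, points$col))
  }
  stopifnot(is.matrix(points), ncol(points) >= 2)
  points[, 1:2, drop = FALSE]
}

#' Fluorescence enrichment in an actin structure
#'
#' Mean signal intensity over the structure mask divided by the mean over
#' the whole cell (synapse) mask; 1 means no enrichment, > 1 enrichment,
#' < 1 depletion.
#'
#' @param signal_frame numeric matrix of the channel of interest.
#' @param structure_mask logical matrix (or a [foci_set]/[fiber_mask]) of
#'   the structure; pixels outside the cell are ignored.
#' @param cell a [cell_mask].
#' @param structure_kind label carried into the result (`"foci"`,
#'   `"fibers"`, ...).
#' @return one-row tibble: `cell_id`, `structure_kind`, `enrichment`.
#'   `NaN` with a warning for an empty structure mask.
#' @export
enrichment <- function(signal_frame, structure_mask, cell,
                       structure_kind = "foci") {
  stopifnot(is.matrix(signal_frame), inherits(cell, "cell_mask"))
  if (inherits(structure_mask, "foci_set")) {
    structure_mask <- structure_mask$labels > 0L
  } else if (inherits(structure_mask, "fiber_mask")) {
    structure_mask <- structure_mask$mask
  }
  m <- structure_mask != 0 & cell$mask
  cell_mean <- mean(signal_frame[cell$mask])
  if (cell_mean == 0) stop("zero mean signal over the cell mask")
  if (!any(m)) {
    warning("empty structure mask; enrichment undefined")
    val <- NaN
  } else {
    val <- mean(signal_frame[m]) / cell_mean
  }
  tibble(cell_id = cell$cell_id, structure_kind = structure_kind,
         enrichment = val)
}

#' Center-overlap colocalization fraction
#'
#' `direction = "regions"`: fraction of regions whose footprint contains at
#' least one point center. `direction = "points"`: fraction of point centers
#' lying on any region pixel. Centers are continuous (row, col) coordinates;
#' containment is pixel membership of the nearest pixel (inclusive at
#' borders).
#'
#' @param regions a [foci_set], [fiber_mask], binary matrix (regions are its
#'   8-connected components) or integer label matrix.
#' @param points data frame with `row`, `col` columns (or 2-column matrix).
#' @param direction `"regions"` or `"points"`.
#' @return a fraction in `[0, 1]`; `NaN` with a warning when there are no
#'   regions (or no points, for the point direction).
#' @export
coloc_fraction <- function(regions, points, direction = c("regions", "points")) {
  direction <- match.arg(direction)
  labels <- regions_labels(regions)
  pts <- points_matrix(points)
  n_regions <- max(labels, 0L)
  if (direction == "regions" && n_regions == 0L) {
    warning("no regions; colocalization fraction undefined")
    return(NaN)
  }
  if (direction == "points" && nrow(pts) == 0L) {
    warning("no points; colocalization fraction undefined")
    return(NaN)
  }
  if (nrow(pts) == 0L) return(0)
  pr <- pmin(pmax(round(pts[, 1]), 1L), nrow(labels))
  pc <- pmin(pmax(round(pts[, 2]), 1L), ncol(labels))
  hit <- labels[cbind(pr, pc)]
  if (direction == "regions") {
    length(unique(hit[hit > 0L])) / n_regions
  } else {
    mean(hit > 0L)
  }
}

# place n non-overlapping discs uniformly inside the cell mask;
# returns a 2-column matrix of centers or NULL on failure
place_random_structures <- function(cell, radii, max_attempts = 10000L) {
  inside <- which(cell$mask)
  nr <- nrow(cell$mask)
  n <- length(radii)
  centers <- matrix(NA_real_, n, 2)
  placed <- 0L
  attempts <- 0L
  while (placed < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    k <- inside[sample.int(length(inside), 1L)]
    cand <- c((k - 1) %% nr + 1, (k - 1) %/% nr + 1)
    ok <- TRUE
    if (placed > 0L) {
      d <- sqrt((centers[seq_len(placed), 1] - cand[1])^2 +
                (centers[seq_len(placed), 2] - cand[2])^2)
      ok <- all(d >= radii[placed + 1L] + radii[seq_len(placed)])
    }
    if (ok) {
      placed <- placed + 1L
      centers[placed, ] <- cand
    }
  }
  if (placed < n) return(NULL)
  centers
}

#' Colocalization against a randomized-placement null
#'
#' Measures both center-overlap fractions between the regions and the point
#' structures, then builds the null by re-placing, in each run, the same
#' number of structures with the same disc footprints uniformly at random
#' inside the cell mask without pairwise overlap (rejection sampling), and
#' recomputing both fractions. The random value is the mean over
#' `n_randomizations` runs (default ten). Deterministic for a given
#' `rng_seed`.
#'
#' @inheritParams coloc_fraction
#' @param cell a [cell_mask].
#' @param points data frame with `row`, `col` and optional `radius_px`
#'   (disc footprint for the non-overlap constraint; default 0).
#' @param n_randomizations number of randomization runs.
#' @param rng_seed integer seed.
#' @return one-row tibble: `cell_id`, `fraction_regions_with_center`
#'   (fraction of regions containing a point center),
#'   `fraction_points_in_regions`, `random_fraction_regions_with_center`,
#'   `random_fraction_points_in_regions`, `n_randomizations`.
#' @export
randomized_coloc <- function(regions, points, cell, n_randomizations = 10L,
                             rng_seed = 1L) {
  stopifnot(inherits(cell, "cell_mask"), n_randomizations >= 1L)
  labels <- regions_labels(regions)
  pts <- points_matrix(points)
  radii <- if (is.data.frame(points) && "radius_px" %in% names(points)) {
    points$radius_px
  } else {
    rep(0, nrow(pts))
  }
  meas_r <- suppressWarnings(coloc_fraction(labels, pts, "regions"))
  meas_p <- suppressWarnings(coloc_fraction(labels, pts, "points"))
  rand_r <- rand_p <- numeric(n_randomizations)
  withr::with_seed(rng_seed, {
    for (run in seq_len(n_randomizations)) {
      centers <- place_random_structures(cell, radii)
      if (is.null(centers)) {
        stop("could not place randomized structures without overlap in cell ",
             cell$cell_id)
      }
      rand_r[run] <- suppressWarnings(
        coloc_fraction(labels, centers, "regions"))
      rand_p[run] <- suppressWarnings(
        coloc_fraction(labels, centers, "points"))
    }
  })
  tibble(cell_id = cell$cell_id,
         fraction_regions_with_center = meas_r,
         fraction_points_in_regions = meas_p,
         random_fraction_regions_with_center = mean(rand_r),
         random_fraction_points_in_regions = mean(rand_p),
         n_randomizations = as.integer(n_randomizations))
}
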