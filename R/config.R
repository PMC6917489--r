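#' Pipeline parameters
#'
#' Collects every tunable numeric parameter of the segmentation, tracking,
#' colocalization, validation and pulling stages. Defaults follow the
#' analysis this package implements: a 325 nm spot/ridge scale (450 nm for
#' the larger structures of Ramos cells), ridge filters at 18-degree
#' increments (10 orientations over 180 degrees), a two-frame persistence
#' filter, ten randomization runs for the colocalization null, and a
#' 5-pixel / 1-frame tolerance for auto-vs-manual matching. Threshold
#' fractions have no universal value (they are calibrated per experiment and
#' held fixed across conditions); the defaults here are starting points and
#' are recorded in run provenance.
#'
#' @param foci_scale_nm FWHM of the isotropic Gaussian spot filter, nm.
#' @param fiber_scale_nm transverse scale of the oriented ridge filter, nm.
#' @param n_orientations number of ridge orientations over 180 degrees.
#' @param foci_threshold_fraction foci response threshold as a fraction of the
#'   cell's mean raw actin intensity.
#' @param fiber_threshold_fraction fiber response threshold, same reference.
#' @param min_focus_area_px minimum focus component area, px.
#' @param max_elongation maximum major/minor axis ratio of a focus.
#' @param link_max_dist_nm tracking gate: maximum frame-to-frame centroid
#'   jump, nm.
#' @param min_track_frames minimum persistence of a track, frames.
#' @param n_randomizations randomization runs for the colocalization null.
#' @param match_tol_px spatial tolerance for detection matching, px.
#' @param match_tol_frames temporal tolerance for detection matching, frames.
#' @param motion_threshold_px net start-to-end motion above which a membrane
#'   structure counts as "moved", px.
#' @param dii_scale_nm FWHM of the band-pass core used for DiI structure
#'   detection, nm.
#' @param dii_threshold_k detection threshold for DiI structures, in robust
#'   (MAD) SDs of the band-pass response inside the cell.
#' @param min_cell_area_um2 minimum segmented cell area, um^2.
#' @param rng_seed integer seed for all randomized steps.
#' @return a named list of class `pipeline_config`.
#' @examples
#' cfg <- pipeline_config(foci_scale_nm = 450)  # Ramos-cell scale
#' cfg$n_orientations
#' @export
pipeline_config <- function(foci_scale_nm = 325,
                            fiber_scale_nm = 325,
                            n_orientations = 10L,
                            foci_threshold_fraction = 1.3,
                            fiber_threshold_fraction = 1.1,
                            min_focus_area_px = 4L,
                            max_elongation = 3,
                            link_max_dist_nm = 500,
                            min_track_frames = 2L,
                            n_randomizations = 10L,
                            match_tol_px = 5,
                            match_tol_frames = 1L,
                            motion_threshold_px = 3,
                            dii_scale_nm = 325,
                            dii_threshold_k = 5,
                            min_cell_area_um2 = 20,
                            rng_seed = 1L) {
  cfg <- list(
    foci_scale_nm = foci_scale_nm, fiber_scale_nm = fiber_scale_nm,
    n_orientations = as.integer(n_orientations),
    foci_threshold_fraction = foci_threshold_fraction,
    fiber_threshold_fraction = fiber_threshold_fraction,
    min_focus_area_px = as.integer(min_focus_area_px),
    max_elongation = max_elongation,
    link_max_dist_nm = link_max_dist_nm,
    min_track_frames = as.integer(min_track_frames),
    n_randomizations = as.integer(n_randomizations),
    match_tol_px = match_tol_px,
    match_tol_frames = as.integer(match_tol_frames),
    motion_threshold_px = motion_threshold_px,
    dii_scale_nm = dii_scale_nm,
    dii_threshold_k = dii_threshold_k,
    min_cell_area_um2 = min_cell_area_um2,
    rng_seed = as.integer(rng_seed)
  )
  pos <- c("foci_scale_nm", "fiber_scale_nm", "foci_threshold_fraction",
           "fiber_threshold_fraction", "max_elongation", "link_max_dist_nm",
           "match_tol_px", "dii_scale_nm", "dii_threshold_k",
           "min_cell_area_um2")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) stop("`", f, "` must be > 0")
  }
  if (cfg$n_orientations < 2L) stop("`n_orientations` must be >= 2")
  if (cfg$min_track_frames < 1L) stop("`min_track_frames` must be >= 1")
  if (cfg$min_focus_area_px < 1L) stop("`min_focus_area_px` must be >= 1")
  if (cfg$n_randomizations < 1L) stop("`n_randomizations` must be >= 1")
  if (cfg$match_tol_frames < 0L) stop("`match_tol_frames` must be >= 0")
  if (cfg$motion_threshold_px < 0) stop("`motion_threshold_px` must be >= 0")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' YAML keys are kebab-case versions of [pipeline_config()] arguments
#' (e.g. `foci-scale-nm`). Unknown keys raise an error.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  names(raw) <- gsub("-", "_", names(raw), fixed = TRUE)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  }
  do.call(pipeline_config, raw)
}

#' Write a pipeline configuration to YAML
#' @param cfg a `pipeline_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- unclass(cfg)
  names(out) <- gsub("_", "-", names(out), fixed = TRUE)
  yaml::write_yaml(out, path)
  invisible(path)
}
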