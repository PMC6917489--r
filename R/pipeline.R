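#' Run the analysis pipeline from a YAML configuration
#'
#' Executes the requested stages in dependency order and writes tabular
#' outputs plus a run manifest to the output directory. Recognised stages:
#' \describe{
#'   \item{simulate}{render a synthetic scene (see [generate_scene()]) and
#'     use it as input for downstream stages; writes the TIFFs and ground
#'     truth under `simulated/`.}
#'   \item{segment}{cell segmentation plus per-frame foci/fiber
#'     segmentation; writes `cells.csv`, `foci.csv`.}
#'   \item{track}{foci tracking, pruning and per-cell dynamics; writes
#'     `tracks.csv`, `track_stats.csv`, `cell_summary.csv`.}
#'   \item{coloc}{enrichment and randomized colocalization of point
#'     structures with foci and fibers on the frame with most points;
#'     writes `coloc.csv`.}
#'   \item{validate}{matches automated foci against reference annotations
#'     (or simulated ground truth); writes `validation.json`.}
#'   \item{pulling}{DiI membrane-pulling detection, dynamic filtering,
#'     association and summary; writes `pulling_events.csv`,
#'     `pulling_summary.csv`.}
#' }
#'
#' Config keys (kebab-case): `out-dir`, `seed`, `stages`, `scene` (scene
#' parameter overrides, used by `simulate`), `params` (pipeline parameter
#' overrides), `inputs` (`actin-tiff`, `dii-tiff`, `pixel-size-nm`,
#' `frame-interval-s`, `points-csv`, `reference-csv`). Unknown keys or
#' stages raise an error before any computation.
#'
#' @param config_path path to the YAML run configuration.
#' @param out_dir optional override of the configured output directory.
#' @return the output directory, invisibly.
#' @export
run_pipeline <- function(config_path, out_dir = NULL) {
  t_start <- proc.time()[["elapsed"]]
  raw <- yaml::read_yaml(config_path)
  if (is.null(raw)) stop("empty pipeline configuration: ", config_path)
  names(raw) <- gsub("-", "_", names(raw))
  known <- c("out_dir", "seed", "stages", "scene", "params", "inputs")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown configuration key(s): ",
                        paste(bad, collapse = ", "))
  stages <- unlist(raw$stages)
  valid_stages <- c("simulate", "segment", "track", "coloc", "validate",
                    "pulling")
  bad <- setdiff(stages, valid_stages)
  if (length(bad)) stop("unknown stage name(s): ", paste(bad, collapse = ", "))
  if (!length(stages)) stop("no stages requested")
  stages <- valid_stages[valid_stages %in% stages]  # dependency order
  out <- if (!is.null(out_dir)) out_dir else raw$out_dir
  if (is.null(out)) stop("`out-dir` is required")
  seed <- if (is.null(raw$seed)) 1L else as.integer(raw$seed)
  cfg_over <- raw$params
  if (!is.null(cfg_over)) names(cfg_over) <- gsub("-", "_", names(cfg_over))
  cfg <- do.call(pipeline_config,
                 c(cfg_over, if (is.null(cfg_over$rng_seed))
                   list(rng_seed = seed)))
  inputs <- raw$inputs
  if (!is.null(inputs)) names(inputs) <- gsub("-", "_", names(inputs))
  needs_input <- !("simulate" %in% stages) &&
    length(intersect(stages, c("segment", "track", "coloc", "validate",
                               "pulling"))) > 0
  if (needs_input && is.null(inputs$actin_tiff)) {
    stop("stages need an actin movie: provide inputs: actin-tiff ",
         "or add the simulate stage")
  }
  if (needs_input && !file.exists(inputs$actin_tiff)) {
    stop("missing input file: ", inputs$actin_tiff)
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = raw, package_version =
                     as.character(utils::packageVersion("synfoci")),
                   seed = seed, stages = stages, timings_s = list(),
                   outputs = character(), input_md5 = list())
  timing <- function(expr, name) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    manifest$timings_s[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  log_msg <- function(...) message("[synfoci] ", ...)
  emit <- function(obj, name) {
    path <- file.path(out, name)
    if (grepl("[.]csv$", name)) {
      write.csv(obj, path, row.names = FALSE)
    } else if (grepl("[.]json$", name)) {
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    }
    manifest$outputs <<- c(manifest$outputs, name)
    path
  }

  scene <- NULL
  actin <- NULL
  dii <- NULL
  if ("simulate" %in% stages) {
    log_msg("stage simulate")
    scene <- timing({
      sc_over <- raw$scene
      if (!is.null(sc_over)) names(sc_over) <- gsub("-", "_", names(sc_over))
      if (is.null(sc_over$rng_seed)) sc_over$rng_seed <- seed
      sp <- do.call(scene_params, sc_over)
      sc <- generate_scene(sp)
      sd_dir <- file.path(out, "simulated")
      dir.create(sd_dir, showWarnings = FALSE)
      write_stack(sc$actin, file.path(sd_dir, "actin.tif"))
      write_stack(sc$dii, file.path(sd_dir, "dii.tif"))
      for (nm in c("foci_events", "foci_positions", "fiber_segments",
                   "dii_events", "dii_positions")) {
        write.csv(sc$truth[[nm]], file.path(sd_dir, paste0(nm, ".csv")),
                  row.names = FALSE)
      }
      sc
    }, "simulate")
    actin <- scene$actin
    dii <- scene$dii
  } else if (!is.null(inputs$actin_tiff)) {
    if (is.null(inputs$pixel_size_nm)) {
      stop("inputs: pixel-size-nm is required with actin-tiff")
    }
    actin <- read_stack(inputs$actin_tiff, inputs$pixel_size_nm,
                        if (is.null(inputs$frame_interval_s)) NA_real_
                        else inputs$frame_interval_s)
    manifest$input_md5[[inputs$actin_tiff]] <-
      unname(tools::md5sum(inputs$actin_tiff))
    if (!is.null(inputs$dii_tiff)) {
      dii <- read_stack(inputs$dii_tiff, inputs$pixel_size_nm,
                        if (is.null(inputs$frame_interval_s)) NA_real_
                        else inputs$frame_interval_s)
      manifest$input_md5[[inputs$dii_tiff]] <-
        unname(tools::md5sum(inputs$dii_tiff))
    }
  }

  cells <- NULL
  seg <- list()
  if (any(c("segment", "track", "coloc", "validate", "pulling") %in% stages)) {
    log_msg("stage segment")
    timing({
      cells <- segment_cells(actin, cfg$min_cell_area_um2)
      if (!length(cells)) stop("no cells found in the actin movie")
      seg <- lapply(cells, function(cm) segment_stack(actin, cm, cfg))
    }, "segment")
    emit(bind_rows(lapply(cells, function(cm) {
      tibble(cell_id = cm$cell_id, area_um2 = cm$area_um2,
             n_px = sum(cm$mask))
    })), "cells.csv")
    emit(bind_rows(lapply(seg, function(s) foci_table(s$foci_by_frame))),
         "foci.csv")
  }

  tracks_by_cell <- NULL
  if ("track" %in% stages) {
    log_msg("stage track")
    timing({
      tracks_by_cell <- lapply(seg, function(s) {
        tr <- link_foci(s$foci_by_frame, cfg$link_max_dist_nm,
                        actin$pixel_size_nm)
        prune_tracks(tr, cfg$min_track_frames)
      })
    }, "track")
    all_tracks <- bind_rows(tracks_by_cell)
    emit(all_tracks, "tracks.csv")
    emit(bind_rows(lapply(tracks_by_cell, track_stats,
                          pixel_size_nm = actin$pixel_size_nm,
                          frame_interval_s = actin$frame_interval_s)),
         "track_stats.csv")
    emit(bind_rows(lapply(seq_along(cells), function(i) {
      summarize_cell(tracks_by_cell[[i]], cells[[i]], n_frames(actin),
                     actin$frame_interval_s, actin$pixel_size_nm)
    })), "cell_summary.csv")
  }

  if ("coloc" %in% stages) {
    log_msg("stage coloc")
    pts <- if (!is.null(inputs$points_csv)) {
      manifest$input_md5[[inputs$points_csv]] <-
        unname(tools::md5sum(inputs$points_csv))
      read_points_csv(inputs$points_csv)
    } else if (!is.null(scene)) {
      sel <- scene$truth$dii_events$event_id[scene$truth$dii_events$dynamic]
      p <- scene$truth$dii_positions
      p[p$event_id %in% sel, c("frame", "row", "col")]
    } else {
      stop("coloc stage needs inputs: points-csv (or the simulate stage)")
    }
    res <- timing({
      counts <- table(pts$frame)
      if (!length(counts)) stop("no point structures available for coloc")
      use_frame <- as.integer(names(counts)[which.max(counts)])
      fpts <- pts[pts$frame == use_frame, ]
      bind_rows(lapply(seq_along(cells), function(i) {
        fs <- seg[[i]]$foci_by_frame[[use_frame]]
        fb <- seg[[i]]$fibers_by_frame[[use_frame]]
        sig <- get_frame(actin, use_frame)
        enr <- bind_rows(
          enrichment(sig, fs, cells[[i]], "foci"),
          enrichment(sig, fb, cells[[i]], "fibers"))
        cl <- randomized_coloc(fs, fpts, cells[[i]],
                               cfg$n_randomizations, cfg$rng_seed)
        cl$frame <- use_frame
        left_join(cl, tidyr::pivot_wider(enr,
                    names_from = "structure_kind",
                    values_from = "enrichment",
                    names_prefix = "enrichment_"),
                  by = "cell_id")
      }))
    }, "coloc")
    emit(res, "coloc.csv")
  }

  if ("validate" %in% stages) {
    log_msg("stage validate")
    ref <- if (!is.null(inputs$reference_csv)) {
      manifest$input_md5[[inputs$reference_csv]] <-
        unname(tools::md5sum(inputs$reference_csv))
      read_points_csv(inputs$reference_csv)
    } else if (!is.null(scene)) {
      tp <- scene$truth$foci_positions
      rec <- scene$truth$foci_events$focus_id[scene$truth$foci_events$recoverable]
      tp[tp$focus_id %in% rec, c("frame", "row", "col")]
    } else {
      stop("validate stage needs inputs: reference-csv (or simulate)")
    }
    rep_ <- timing({
      auto <- bind_rows(lapply(seg, function(s) foci_table(s$foci_by_frame)))
      match_detections(ref, auto, cfg$match_tol_px, cfg$match_tol_frames)
    }, "validate")
    emit(as.list(as.data.frame(rep_)), "validation.json")
  }

  if ("pulling" %in% stages) {
    log_msg("stage pulling")
    if (is.null(dii)) stop("pulling stage needs inputs: dii-tiff (or simulate)")
    res <- timing({
      per_cell <- lapply(seq_along(cells), function(i) {
        ser <- detect_membrane_structures(dii, cells[[i]], cfg)
        ev <- track_and_filter_dynamic(ser, cfg$motion_threshold_px,
                                       cfg$link_max_dist_nm,
                                       dii$pixel_size_nm)
        ev <- associate_events(ev, seg[[i]]$foci_by_frame,
                               seg[[i]]$fibers_by_frame)
        attr(ev, "cell_id") <- cells[[i]]$cell_id
        summ <- summarize_pulling(ev, cells[[i]], seg[[i]]$foci_by_frame,
                                  seg[[i]]$fibers_by_frame)
        ev$events$cell_id <- cells[[i]]$cell_id
        list(events = ev$events, summary = summ)
      })
      list(events = bind_rows(lapply(per_cell, `[[`, "events")),
           summary = bind_rows(lapply(per_cell, `[[`, "summary")))
    }, "pulling")
    emit(res$events, "pulling_events.csv")
    emit(res$summary, "pulling_summary.csv")
  }

  manifest$timings_s$total <- round(proc.time()[["elapsed"]] - t_start, 3)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg("done: ", out)
  invisible(out)
}

#' Read a point-structure CSV
#'
#' Expected columns: `frame`, `row_px`, `col_px`, optional `radius_px`
#' (the `frame,row,col` spelling is also accepted).
#'
#' @param path CSV path.
#' @return tibble with `frame`, `row`, `col` (and `radius_px` if present).
#' @export
read_points_csv <- function(path) {
  d <- as_tibble(read.csv(path))
  if (all(c("row_px", "col_px") %in% names(d))) {
    d$row <- d$row_px; d$col <- d$col_px
  }
  if (!all(c("frame", "row", "col") %in% names(d))) {
    stop("point CSV needs columns frame, row_px, col_px")
  }
  keep <- intersect(c("frame", "row", "col", "radius_px"), names(d))
  d[, keep]
}
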