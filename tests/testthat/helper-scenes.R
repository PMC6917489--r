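# Shared fixtures, built in code and cached for the test run.

.scene_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .scene_cache)) {
    assign(key, force(expr), envir = .scene_cache)
  }
  get(key, envir = .scene_cache)
}

# small foci+fibers scene matching the fixture-suite geometry
small_scene_params <- function(...) {
  base <- list(image_size_px = 128L, n_frames = 30L, cell_radius_um = 4.5,
               n_fibers = 6L, fiber_length_um = 2,
               dii_event_rate_per_frame = 0.3, dii_event_mean_frames = 8,
               dii_static_blemish_count = 3L)
  do.call(scene_params, utils::modifyList(base, list(...)))
}

small_scene <- function(seed = 11L) {
  cached(paste0("small_", seed), generate_scene(small_scene_params(rng_seed = seed)))
}

# scene + full segmentation for the first cell
small_segmented <- function(seed = 11L) {
  cached(paste0("smallseg_", seed), {
    sc <- small_scene(seed)
    cfg <- pipeline_config()
    cells <- segment_cells(sc$actin, cfg$min_cell_area_um2)
    seg <- segment_stack(sc$actin, cells[[1]], cfg)
    list(scene = sc, cfg = cfg, cell = cells[[1]], seg = seg)
  })
}

# pulling scene: sparser foci, more DiI events (fixture-suite settings)
pulling_scene_params <- function(seed = 4L) {
  small_scene_params(foci_birth_rate_per_um2_per_s = 0.06,
                     dii_event_rate_per_frame = 0.7, rng_seed = seed)
}

pulling_segmented <- function(seed = 4L) {
  cached(paste0("pull_", seed), {
    sc <- generate_scene(pulling_scene_params(seed))
    cfg <- pipeline_config()
    cells <- segment_cells(sc$actin, cfg$min_cell_area_um2)
    seg <- segment_stack(sc$actin, cells[[1]], cfg)
    list(scene = sc, cfg = cfg, cell = cells[[1]], seg = seg)
  })
}

# the reference study movie (256 x 256, 200 frames, default parameters)
default_movie_analysis <- function(seed = 1L) {
  cached(paste0("movie_", seed), {
    sc <- generate_scene(scene_params(rng_seed = seed))
    cfg <- pipeline_config()
    cells <- segment_cells(sc$actin, cfg$min_cell_area_um2)
    seg <- segment_stack(sc$actin, cells[[1]], cfg)
    tracks <- prune_tracks(
      link_foci(seg$foci_by_frame, cfg$link_max_dist_nm,
                sc$actin$pixel_size_nm),
      cfg$min_track_frames)
    list(scene = sc, cfg = cfg, cell = cells[[1]], seg = seg,
         tracks = tracks)
  })
}

# direct-sum 2-D convolution with mirror-reflected boundary (oracle):
# accumulates kernel-element by kernel-element over shifted copies, with no
# FFT anywhere
brute_convolve <- function(frame, kernel) {
  nr <- nrow(frame); nc <- ncol(frame)
  kr <- (nrow(kernel) - 1L) %/% 2L
  kc <- (ncol(kernel) - 1L) %/% 2L
  reflect <- function(i, n) {
    i <- ((i - 1L) %% (2L * n)) + 1L
    ifelse(i > n, 2L * n - i + 1L, i)
  }
  out <- matrix(0, nr, nc)
  for (dr in -kr:kr) {
    ridx <- reflect(seq_len(nr) + dr, nr)
    for (dc in -kc:kc) {
      cidx <- reflect(seq_len(nc) + dc, nc)
      out <- out + kernel[dr + kr + 1L, dc + kc + 1L] * frame[ridx, cidx]
    }
  }
  out
}

# exhaustive gated one-to-one matching: maximum cardinality, then minimum
# total distance (oracle for the frame-to-frame linker)
brute_match <- function(a, b, gate) {
  na_ <- nrow(a); nb <- nrow(b)
  best <- list(card = -1L, cost = Inf, m = rep(NA_integer_, na_))
  d <- if (na_ && nb) {
    sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
  } else matrix(0, 0, 0)
  recurse <- function(i, used_b, m, card, cost) {
    if (i > na_) {
      if (card > best$card ||
          (card == best$card && cost < best$cost - 1e-12)) {
        best <<- list(card = card, cost = cost, m = m)
      }
      return(invisible())
    }
    recurse(i + 1L, used_b, m, card, cost)           # leave i unmatched
    for (j in seq_len(nb)) {
      if (!used_b[j] && d[i, j] <= gate) {
        used_b[j] <- TRUE; m[i] <- j
        recurse(i + 1L, used_b, m, card + 1L, cost + d[i, j])
        used_b[j] <- FALSE; m[i] <- NA_integer_
      }
    }
  }
  recurse(1L, rep(FALSE, nb), rep(NA_integer_, na_), 0L, 0)
  best$m
}

# link a detection table with the exhaustive matcher (oracle linker)
brute_link <- function(det, gate_px) {
  det <- det[order(det$frame, det$row, det$col), ]
  det$track_id <- 0L
  frames <- sort(unique(det$frame))
  next_id <- 1L
  open_idx <- integer()
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    rows <- which(det$frame == f)
    contiguous <- fi > 1L && frames[fi - 1L] == f - 1L
    if (!contiguous) open_idx <- integer()
    m <- if (length(open_idx)) {
      brute_match(cbind(det$row[open_idx], det$col[open_idx]),
                  cbind(det$row[rows], det$col[rows]), gate_px)
    } else integer()
    new_open <- integer()
    matched <- rep(FALSE, length(rows))
    for (k in seq_along(m)) {
      if (!is.na(m[k])) {
        det$track_id[rows[m[k]]] <- det$track_id[open_idx[k]]
        matched[m[k]] <- TRUE
        new_open <- c(new_open, rows[m[k]])
      }
    }
    for (k in which(!matched)) {
      det$track_id[rows[k]] <- next_id
      next_id <- next_id + 1L
      new_open <- c(new_open, rows[k])
    }
    open_idx <- new_open
  }
  det
}

# canonical serialization of a track decomposition (order-free comparison)
track_signature <- function(tracks) {
  sp <- split(tracks[, c("frame", "row", "col")], tracks$track_id)
  sig <- vapply(sp, function(d) {
    d <- d[order(d$frame), ]
    paste(sprintf("%d:%.6f:%.6f", d$frame, d$row, d$col), collapse = "|")
  }, "")
  sort(unname(sig))
}
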