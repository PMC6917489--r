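#' Parameters of a synthetic TIRF scene
#'
#' Describes a Lifeact-like actin channel (a spread, stationary cell
#' containing transient diffusing Gaussian foci and static linear fiber
#' ridges over a flat cytoplasmic background) and a DiI channel (appearing
#' membrane-deformation spots plus preexisting static blemishes), both with
#' Poisson shot noise and Gaussian read noise quantized to camera digital
#' numbers. Defaults describe the reference study conditions used throughout
#' the package's tests: 100 nm pixels, 100 ms frames, a 200-frame movie of
#' an 8 um-radius cell, foci of 325 nm FWHM born at a rate giving a
#' steady-state density of about 0.15 foci/um^2 with an exponential mean
#' lifetime of 3 s, and amplitudes giving a peak signal-to-noise ratio of
#' roughly 8. The default density keeps planted spots individually
#' resolvable at the 325 nm/100 nm px optical scale (neighbours closer than
#' about 4 px merge into one detection), which is what makes planted-truth
#' recovery a meaningful benchmark; denser, paper-like fields are available
#' by raising the birth rate.
#'
#' @param image_size_px image side length, px.
#' @param pixel_size_nm pixel edge length, nm.
#' @param frame_interval_s frame interval, s.
#' @param n_frames number of frames.
#' @param cell_radius_um cell (synapse) disc radius, um.
#' @param foci_birth_rate_per_um2_per_s areal focus birth rate.
#' @param foci_lifetime_mean_s exponential mean focus lifetime, s.
#' @param foci_diffusion_um2_per_s focus diffusion coefficient.
#' @param foci_amplitude peak amplitude of a focus above background, DN.
#' @param foci_width_nm focus FWHM, nm.
#' @param initial_foci_count `NA` for a Poisson steady-state initial
#'   population, or an exact count of foci present from frame 1.
#' @param n_fibers number of static fiber segments.
#' @param fiber_length_um fiber segment length, um.
#' @param fiber_width_nm fiber transverse FWHM, nm.
#' @param fiber_amplitude fiber ridge amplitude, DN.
#' @param background_level in-cell background, DN.
#' @param outside_level off-cell background, DN.
#' @param poisson_noise apply Poisson shot noise?
#' @param gain camera gain for the shot-noise model, DN per photon.
#' @param read_noise_sd Gaussian read noise SD, DN; 0 disables.
#' @param dii_background in-cell DiI background, DN.
#' @param dii_amplitude DiI structure peak amplitude, DN.
#' @param dii_event_rate_per_frame birth rate of dynamic DiI events per
#'   frame (events appear from frame 2 on).
#' @param dii_event_mean_frames mean DiI event duration, frames (>= 2).
#' @param dii_static_blemish_count preexisting static DiI structures present
#'   from frame 1.
#' @param rng_seed mandatory integer seed; the scene is fully determined by
#'   it.
#' @return a named list of class `scene_params`.
#' @export
scene_params <- function(image_size_px = 256L,
                         pixel_size_nm = 100,
                         frame_interval_s = 0.1,
                         n_frames = 200L,
                         cell_radius_um = 8,
                         foci_birth_rate_per_um2_per_s = 0.05,
                         foci_lifetime_mean_s = 3,
                         foci_diffusion_um2_per_s = 0.002,
                         foci_amplitude = 150,
                         foci_width_nm = 325,
                         initial_foci_count = NA_integer_,
                         n_fibers = 12L,
                         fiber_length_um = 3,
                         fiber_width_nm = 325,
                         fiber_amplitude = 40,
                         background_level = 100,
                         outside_level = 5,
                         poisson_noise = TRUE,
                         gain = 1,
                         read_noise_sd = 3,
                         dii_background = 100,
                         dii_amplitude = 150,
                         dii_event_rate_per_frame = 0.15,
                         dii_event_mean_frames = 12,
                         dii_static_blemish_count = 5L,
                         rng_seed = 1L) {
  p <- as.list(environment())
  nonneg <- c("foci_birth_rate_per_um2_per_s", "foci_diffusion_um2_per_s",
              "foci_amplitude", "fiber_amplitude", "background_level",
              "outside_level", "read_noise_sd", "dii_amplitude",
              "dii_event_rate_per_frame", "dii_static_blemish_count")
  for (f in nonneg) if (p[[f]] < 0) stop("`", f, "` must be >= 0")
  pos <- c("image_size_px", "pixel_size_nm", "frame_interval_s", "n_frames",
           "cell_radius_um", "foci_lifetime_mean_s", "foci_width_nm",
           "fiber_length_um", "fiber_width_nm", "gain",
           "dii_event_mean_frames")
  for (f in pos) if (p[[f]] <= 0) stop("`", f, "` must be > 0")
  if (is.null(p$rng_seed) || is.na(p$rng_seed)) stop("`rng_seed` is mandatory")
  p$image_size_px <- as.integer(p$image_size_px)
  p$n_frames <- as.integer(p$n_frames)
  p$n_fibers <- as.integer(p$n_fibers)
  p$dii_static_blemish_count <- as.integer(p$dii_static_blemish_count)
  p$rng_seed <- as.integer(p$rng_seed)
  structure(p, class = "scene_params")
}

# add a Gaussian spot at continuous center (r0, c0) to image `img`
add_spot <- function(img, r0, c0, amplitude, sigma_px, window_sigmas = 4) {
  w <- ceiling(window_sigmas * sigma_px)
  rr <- max(1L, floor(r0 - w)):min(nrow(img), ceiling(r0 + w))
  cc <- max(1L, floor(c0 - w)):min(ncol(img), ceiling(c0 + w))
  if (!length(rr) || !length(cc)) return(img)
  g <- outer(exp(-(rr - r0)^2 / (2 * sigma_px^2)),
             exp(-(cc - c0)^2 / (2 * sigma_px^2)))
  img[rr, cc] <- img[rr, cc] + amplitude * g
  img
}

# Gaussian ridge along segment (r0,c0)-(r1,c1), added over its bounding box
add_ridge <- function(img, r0, c0, r1, c1, amplitude, sigma_px) {
  w <- ceiling(4 * sigma_px)
  rr <- max(1L, floor(min(r0, r1) - w)):min(nrow(img), ceiling(max(r0, r1) + w))
  cc <- max(1L, floor(min(c0, c1) - w)):min(ncol(img), ceiling(max(c0, c1) + w))
  pr <- matrix(rep(rr, times = length(cc)), length(rr))
  pc <- matrix(rep(cc, each = length(rr)), length(rr))
  vx <- r1 - r0; vy <- c1 - c0
  len2 <- vx^2 + vy^2
  tt <- pmin(pmax(((pr - r0) * vx + (pc - c0) * vy) / len2, 0), 1)
  d2 <- (pr - (r0 + tt * vx))^2 + (pc - (c0 + tt * vy))^2
  img[rr, cc] <- img[rr, cc] + amplitude * exp(-d2 / (2 * sigma_px^2))
  img
}

point_segment_dist <- function(p, seg) {
  vx <- seg[3] - seg[1]; vy <- seg[4] - seg[2]
  len2 <- vx^2 + vy^2
  tt <- if (len2 == 0) 0 else
    min(max(((p[1] - seg[1]) * vx + (p[2] - seg[2]) * vy) / len2, 0), 1)
  sqrt((p[1] - (seg[1] + tt * vx))^2 + (p[2] - (seg[2] + tt * vy))^2)
}

apply_camera_noise <- function(img, params) {
  if (params$poisson_noise) {
    counts <- rpois(length(img), pmax(img, 0) * params$gain) / params$gain
    img <- matrix(counts, nrow(img), ncol(img))
  }
  if (params$read_noise_sd > 0) {
    img <- img + matrix(rnorm(length(img), 0, params$read_noise_sd),
                        nrow(img), ncol(img))
  }
  if (params$poisson_noise || params$read_noise_sd > 0) {
    img <- pmin(pmax(round(img), 0), 65535)
  }
  img
}

#' Generate a synthetic two-channel TIRF movie with ground truth
#'
#' Renders the actin and DiI channels described by [scene_params()] and
#' returns, alongside the two [frame_stack]s, the complete ground truth:
#' every planted focus (birth/death frames and per-frame true centers),
#' fiber segment endpoints, every DiI structure (dynamic flag and true
#' actin-association label) and the true cell mask. Identical parameters
#' (including `rng_seed`) yield identical pixel arrays.
#'
#' Foci are born by a Poisson process at the stated areal rate (plus a
#' steady-state initial population, unless `initial_foci_count` fixes it),
#' live exponential lifetimes discretized to frames, and diffuse with the
#' stated coefficient. Dynamic DiI events appear strictly after frame 1 and
#' are planted either riding a focus, on a fiber, or on clear background
#' (the true association label); static blemishes are present from frame 1
#' and never move.
#'
#' @param params a [scene_params()] object.
#' @return list with elements `actin`, `dii` ([frame_stack]s), `truth`
#'   (list of tibbles `foci_events`, `foci_positions`, `fiber_segments`,
#'   `dii_events`, `dii_positions`, plus logical matrix `cell_mask_true`),
#'   and `params`.
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  withr::with_seed(params$rng_seed, generate_scene_impl(params))
}

generate_scene_impl <- function(p) {
  n <- p$image_size_px
  ctr <- (n + 1) / 2
  r_px <- p$cell_radius_um * 1000 / p$pixel_size_nm
  if (r_px + 4 > n / 2) stop("cell radius does not fit in the image")
  coord <- seq_len(n)
  dist2 <- outer((coord - ctr)^2, (coord - ctr)^2, "+")
  cell <- dist2 <= r_px^2
  area_um2 <- sum(cell) * (p$pixel_size_nm / 1000)^2
  sigma_spot <- p$foci_width_nm / (2.355 * p$pixel_size_nm)
  sigma_fiber <- p$fiber_width_nm / (2.355 * p$pixel_size_nm)
  tdt <- p$frame_interval_s
  tau <- p$foci_lifetime_mean_s

  # --- fibers (static) ---
  fibers <- NULL
  if (p$n_fibers > 0L) {
    half <- p$fiber_length_um * 1000 / p$pixel_size_nm / 2
    segs <- matrix(NA_real_, p$n_fibers, 4)
    for (i in seq_len(p$n_fibers)) {
      placed <- FALSE
      for (a in seq_len(1000L)) {
        rad <- sqrt(runif(1)) * 0.75 * r_px
        phi <- runif(1, 0, 2 * pi)
        cx <- ctr + rad * cos(phi); cy <- ctr + rad * sin(phi)
        th <- runif(1, 0, pi)
        e1 <- c(cx - half * cos(th), cy - half * sin(th))
        e2 <- c(cx + half * cos(th), cy + half * sin(th))
        if (sqrt((e1[1] - ctr)^2 + (e1[2] - ctr)^2) < 0.92 * r_px &&
            sqrt((e2[1] - ctr)^2 + (e2[2] - ctr)^2) < 0.92 * r_px) {
          segs[i, ] <- c(e1, e2); placed <- TRUE; break
        }
      }
      if (!placed) stop("could not place fiber ", i, "; density too high")
    }
    fibers <- tibble(fiber_id = seq_len(p$n_fibers), r0 = segs[, 1],
                     c0 = segs[, 2], r1 = segs[, 3], c1 = segs[, 4])
  } else {
    fibers <- tibble(fiber_id = integer(), r0 = numeric(), c0 = numeric(),
                     r1 = numeric(), c1 = numeric())
  }

  base <- matrix(p$outside_level, n, n)
  base[cell] <- p$background_level
  if (nrow(fibers)) {
    for (i in seq_len(nrow(fibers))) {
      base <- add_ridge(base, fibers$r0[i], fibers$c0[i], fibers$r1[i],
                        fibers$c1[i], p$fiber_amplitude, sigma_fiber)
    }
  }

  # --- foci birth/death/positions ---
  margin <- 6
  sample_pos <- function(k) {
    rad <- sqrt(runif(k)) * (r_px - margin)
    phi <- runif(k, 0, 2 * pi)
    cbind(ctr + rad * cos(phi), ctr + rad * sin(phi))
  }
  n0 <- if (is.na(p$initial_foci_count)) {
    rpois(1, p$foci_birth_rate_per_um2_per_s * area_um2 * tau)
  } else {
    as.integer(p$initial_foci_count)
  }
  births <- rep(1L, n0)
  if (p$foci_birth_rate_per_um2_per_s > 0 && p$n_frames >= 2L) {
    per_frame <- rpois(p$n_frames - 1L,
                       p$foci_birth_rate_per_um2_per_s * area_um2 * tdt)
    births <- c(births, rep(seq.int(2L, p$n_frames), per_frame))
  }
  n_foci <- length(births)
  life_frames <- pmax(1L, ceiling(rexp(n_foci, rate = 1 / tau) / tdt))
  death_true <- births + life_frames - 1L
  death_obs <- pmin(death_true, p$n_frames)
  step_sd <- sqrt(2 * p$foci_diffusion_um2_per_s * tdt) * 1000 /
    p$pixel_size_nm
  foci_pos <- vector("list", n_foci)
  if (n_foci) {
    starts <- sample_pos(n_foci)
    for (i in seq_len(n_foci)) {
      nf <- death_obs[i] - births[i] + 1L
      dr <- c(0, cumsum(rnorm(nf - 1L, 0, step_sd)))
      dc <- c(0, cumsum(rnorm(nf - 1L, 0, step_sd)))
      foci_pos[[i]] <- tibble(
        focus_id = i, frame = seq.int(births[i], death_obs[i]),
        row = pmin(pmax(starts[i, 1] + dr, 1 + margin / 2), n - margin / 2),
        col = pmin(pmax(starts[i, 2] + dc, 1 + margin / 2), n - margin / 2))
    }
  }
  foci_positions <- if (n_foci) bind_rows(foci_pos) else
    tibble(focus_id = integer(), frame = integer(), row = numeric(),
           col = numeric())
  foci_events <- tibble(
    focus_id = seq_len(n_foci), birth_frame = births,
    death_frame = death_obs, n_frames_visible = death_obs - births + 1L,
    censored = death_true > p$n_frames,
    recoverable = (death_obs - births + 1L) >= 2L)

  # --- render actin ---
  actin_px <- array(0, c(p$n_frames, n, n))
  pos_by_frame <- if (nrow(foci_positions)) {
    split(foci_positions, foci_positions$frame)
  } else list()
  for (t in seq_len(p$n_frames)) {
    fr <- base
    key <- as.character(t)
    if (!is.null(pos_by_frame[[key]])) {
      pp <- pos_by_frame[[key]]
      for (q in seq_len(nrow(pp))) {
        fr <- add_spot(fr, pp$row[q], pp$col[q], p$foci_amplitude, sigma_spot)
      }
    }
    actin_px[t, , ] <- apply_camera_noise(fr, p)
  }

  # --- DiI structures ---
  seg_mat <- as.matrix(fibers[, c("r0", "c0", "r1", "c1")])
  min_fiber_dist <- function(pt) {
    if (!nrow(seg_mat)) return(Inf)
    min(vapply(seq_len(nrow(seg_mat)),
               function(i) point_segment_dist(pt, seg_mat[i, ]), 0))
  }
  # focus positions indexed by frame for clearance checks
  foci_frame_pos <- pos_by_frame
  clear_of_foci <- function(pt, frames, dmin) {
    for (t in frames) {
      pp <- foci_frame_pos[[as.character(t)]]
      if (!is.null(pp) && nrow(pp)) {
        if (min(sqrt((pp$row - pt[1])^2 + (pp$col - pt[2])^2)) < dmin) {
          return(FALSE)
        }
      }
    }
    TRUE
  }
  dii_ev <- list(); dii_pts <- list()
  ev_id <- 0L
  # DiI structures live in the cell core: detection excludes a rim near the
  # cell edge (the edge itself is a band-pass feature), so structures planted
  # there would be invisible or flicker
  core_r <- max(r_px - 12, 0.5 * r_px)
  in_core <- function(rows, cols) {
    all((rows - ctr)^2 + (cols - ctr)^2 < core_r^2)
  }
  sample_core_pos <- function() {
    rad <- sqrt(runif(1)) * (core_r - 1)
    phi <- runif(1, 0, 2 * pi)
    c(ctr + rad * cos(phi), ctr + rad * sin(phi))
  }
  # planted DiI structures keep >= 12 px mutual clearance while (nearly)
  # co-occurring, so each maps to one resolvable track
  clear_of_events <- function(rows, cols, frames, dmin = 10) {
    for (k in seq_len(ev_id)) {
      other <- dii_pts[[k]]
      sel <- other$frame >= frames[1] - 2L &
        other$frame <= frames[length(frames)] + 2L
      if (!any(sel)) next
      d <- sqrt(outer(rows, other$row[sel], "-")^2 +
                outer(cols, other$col[sel], "-")^2)
      if (min(d) < dmin) return(FALSE)
    }
    TRUE
  }
  add_event <- function(type, dynamic, assoc, frames, rows, cols) {
    ev_id <<- ev_id + 1L
    dii_ev[[ev_id]] <<- tibble(
      event_id = ev_id, type = type, dynamic = dynamic,
      birth_frame = frames[1], death_frame = frames[length(frames)],
      true_association = assoc)
    dii_pts[[ev_id]] <<- tibble(event_id = ev_id, frame = frames,
                                row = rows, col = cols)
  }
  # preexisting static blemishes: frame 1 .. T, never move
  if (p$dii_static_blemish_count > 0L) {
    for (b in seq_len(p$dii_static_blemish_count)) {
      ok <- FALSE
      for (a in seq_len(500L)) {
        pt <- sample_core_pos()
        if (clear_of_events(pt[1], pt[2], c(1L, p$n_frames))) {
          ok <- TRUE; break
        }
      }
      if (!ok) stop("could not place static DiI blemish; density too high")
      add_event("static", FALSE, "none", seq_len(p$n_frames),
                rep(pt[1], p$n_frames), rep(pt[2], p$n_frames))
    }
  }
  # dynamic events appear strictly after frame 1
  if (p$dii_event_rate_per_frame > 0 && p$n_frames >= 3L) {
    n_births <- rpois(p$n_frames - 1L, p$dii_event_rate_per_frame)
    for (t in seq.int(2L, p$n_frames)) {
      for (b in seq_len(n_births[t - 1L])) {
        dur <- min(2L + rpois(1, max(p$dii_event_mean_frames - 2, 0.01)),
                   p$n_frames - t + 1L)
        if (dur < 2L) next
        type <- sample(c("foci", "fibers", "none"), 1,
                       prob = c(0.4, 0.3, 0.3))
        frames <- seq.int(t, t + dur - 1L)
        if (type == "foci") {
          cand <- which(foci_events$birth_frame <= t &
                          foci_events$death_frame >= t + dur - 1L)
          cand <- cand[vapply(cand, function(i) {
            pp <- foci_pos[[i]]
            all(vapply(seq_len(nrow(pp)), function(q) {
              min_fiber_dist(c(pp$row[q], pp$col[q])) > 8
            }, TRUE))
          }, TRUE)]
          if (!length(cand)) next
          cand <- cand[vapply(cand, function(i) {
            pp <- foci_pos[[i]]
            sel <- pp$frame %in% frames
            in_core(pp$row[sel], pp$col[sel]) &&
              clear_of_events(pp$row[sel], pp$col[sel], frames)
          }, TRUE)]
          if (!length(cand)) next
          i <- cand[sample.int(length(cand), 1L)]
          pp <- foci_pos[[i]]
          sel <- pp$frame %in% frames
          add_event("dynamic", TRUE, "foci", pp$frame[sel], pp$row[sel],
                    pp$col[sel])
        } else if (type == "fibers") {
          if (!nrow(seg_mat)) next
          ok <- FALSE
          for (a in seq_len(200L)) {
            i <- sample.int(nrow(seg_mat), 1L)
            u <- runif(1, 0.1, 0.9)
            pt <- c(seg_mat[i, 1] + u * (seg_mat[i, 3] - seg_mat[i, 1]),
                    seg_mat[i, 2] + u * (seg_mat[i, 4] - seg_mat[i, 2]))
            # isolated stretch of a single fiber: away from crossings,
            # where the spot filter wins and the truth label is ambiguous
            d_other <- if (nrow(seg_mat) > 1L) {
              min(vapply(setdiff(seq_len(nrow(seg_mat)), i),
                         function(k) point_segment_dist(pt, seg_mat[k, ]), 0))
            } else Inf
            if (d_other > 8 && in_core(pt[1], pt[2]) &&
                clear_of_foci(pt, frames, 10) &&
                clear_of_events(pt[1], pt[2], frames)) { ok <- TRUE; break }
          }
          if (!ok) next
          add_event("dynamic", TRUE, "fibers", frames,
                    rep(pt[1], dur), rep(pt[2], dur))
        } else {
          ok <- FALSE
          for (a in seq_len(200L)) {
            pt <- sample_core_pos()
            if (min_fiber_dist(pt) > 10 && clear_of_foci(pt, frames, 10) &&
                clear_of_events(pt[1], pt[2], frames)) {
              ok <- TRUE; break
            }
          }
          if (!ok) next
          add_event("dynamic", TRUE, "none", frames,
                    rep(pt[1], dur), rep(pt[2], dur))
        }
      }
    }
  }
  dii_events <- if (ev_id) bind_rows(dii_ev) else
    tibble(event_id = integer(), type = character(), dynamic = logical(),
           birth_frame = integer(), death_frame = integer(),
           true_association = character())
  dii_positions <- if (ev_id) bind_rows(dii_pts) else
    tibble(event_id = integer(), frame = integer(), row = numeric(),
           col = numeric())

  # --- render DiI ---
  dii_base <- matrix(p$outside_level, n, n)
  dii_base[cell] <- p$dii_background
  dii_px <- array(0, c(p$n_frames, n, n))
  dpts_by_frame <- if (nrow(dii_positions)) {
    split(dii_positions, dii_positions$frame)
  } else list()
  for (t in seq_len(p$n_frames)) {
    fr <- dii_base
    pp <- dpts_by_frame[[as.character(t)]]
    if (!is.null(pp)) {
      for (q in seq_len(nrow(pp))) {
        fr <- add_spot(fr, pp$row[q], pp$col[q], p$dii_amplitude, sigma_spot)
      }
    }
    dii_px[t, , ] <- apply_camera_noise(fr, p)
  }

  list(
    actin = frame_stack(actin_px, p$pixel_size_nm, p$frame_interval_s,
                        "Lifeact (synthetic)"),
    dii = frame_stack(dii_px, p$pixel_size_nm, p$frame_interval_s,
                      "DiI (synthetic)"),
    truth = list(foci_events = foci_events,
                 foci_positions = foci_positions,
                 fiber_segments = fibers,
                 dii_events = dii_events,
                 dii_positions = dii_positions,
                 cell_mask_true = cell),
    params = p)
}

#' Write the canonical fixture suite
#'
#' Renders a set of small named scenes with ground truth to disk:
#' `empty` (no structures, no noise), `single_focus` (one immortal,
#' immobile focus), `foci_fibers` (foci and fibers), `pulling` (DiI channel
#' with dynamic events and static blemishes), `fibers_only` (Arp2/3-
#' inhibited-like: no foci) and `foci_only` (formin-inhibited-like: no
#' fibers). Each fixture directory contains `actin.tif` (and `dii.tif`),
#' ground-truth CSVs, and a `params.yaml` snapshot. Deterministic per seed.
#'
#' @param out_dir output directory (created if needed).
#' @param seed base integer seed; each fixture derives its own from it.
#' @return named list of fixture directories, invisibly.
#' @export
render_fixture_suite <- function(out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  small <- function(...) {
    base <- list(image_size_px = 128L, n_frames = 30L, cell_radius_um = 4.5,
                 n_fibers = 6L, fiber_length_um = 2,
                 dii_event_rate_per_frame = 0.3, dii_event_mean_frames = 8,
                 dii_static_blemish_count = 3L)
    do.call(scene_params, utils::modifyList(base, list(...)))
  }
  specs <- list(
    empty = small(foci_birth_rate_per_um2_per_s = 0, initial_foci_count = 0L,
                  n_fibers = 0L, dii_event_rate_per_frame = 0,
                  dii_static_blemish_count = 0L, poisson_noise = FALSE,
                  read_noise_sd = 0, rng_seed = seed),
    single_focus = small(foci_birth_rate_per_um2_per_s = 0,
                         initial_foci_count = 1L,
                         foci_lifetime_mean_s = 1e6,
                         foci_diffusion_um2_per_s = 0, n_fibers = 0L,
                         dii_event_rate_per_frame = 0,
                         dii_static_blemish_count = 0L,
                         rng_seed = seed + 1L),
    foci_fibers = small(rng_seed = seed + 2L),
    # fewer foci and more DiI events so planted events of every association
    # class fit in the small cell with clearance from other structures
    pulling = small(foci_birth_rate_per_um2_per_s = 0.06,
                    dii_event_rate_per_frame = 0.7,
                    rng_seed = seed + 3L),
    fibers_only = small(foci_birth_rate_per_um2_per_s = 0,
                        initial_foci_count = 0L, rng_seed = seed + 4L),
    foci_only = small(n_fibers = 0L, rng_seed = seed + 5L))
  dirs <- list()
  for (nm in names(specs)) {
    d <- file.path(out_dir, nm)
    dir.create(d, showWarnings = FALSE)
    sc <- generate_scene(specs[[nm]])
    write_stack(sc$actin, file.path(d, "actin.tif"))
    write_stack(sc$dii, file.path(d, "dii.tif"))
    tr <- sc$truth
    write.csv(tr$foci_events, file.path(d, "foci_events.csv"),
              row.names = FALSE)
    write.csv(tr$foci_positions, file.path(d, "foci_positions.csv"),
              row.names = FALSE)
    write.csv(tr$fiber_segments, file.path(d, "fiber_segments.csv"),
              row.names = FALSE)
    write.csv(tr$dii_events, file.path(d, "dii_events.csv"),
              row.names = FALSE)
    write.csv(tr$dii_positions, file.path(d, "dii_positions.csv"),
              row.names = FALSE)
    write_stack(frame_stack(tr$cell_mask_true * 1,
                            specs[[nm]]$pixel_size_nm),
                file.path(d, "cell_mask.tif"))
    pl <- unclass(specs[[nm]])
    pl$initial_foci_count <-
      if (is.na(pl$initial_foci_count)) "auto" else pl$initial_foci_count
    yaml::write_yaml(pl, file.path(d, "params.yaml"))
    dirs[[nm]] <- d
  }
  invisible(dirs)
}
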