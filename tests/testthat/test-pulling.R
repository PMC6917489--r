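test_that("flat DiI frames yield no structures; planted spots are found", {
  cfg <- pipeline_config()
  cell <- cell_mask({
    co <- seq_len(96)
    outer((co - 48)^2, (co - 48)^2, "+") <= 35^2
  }, 100)
  flat <- frame_stack(array(100, c(2, 96, 96)), 100, 0.1)
  expect_equal(nrow(detect_membrane_structures(flat, cell, cfg)), 0L)

  # one bright spot, SNR ~10 relative to Poisson noise
  f <- matrix(100, 96, 96)
  f <- synfoci:::add_spot(f, 40.3, 52.6, 150, 1.4)
  withr::with_seed(3, {
    noisy <- matrix(rpois(96 * 96, f), 96, 96)
  })
  one <- detect_membrane_structures(frame_stack(noisy, 100, 0.1), cell, cfg)
  expect_equal(nrow(one), 1L)
  expect_lt(sqrt((one$row - 40.3)^2 + (one$col - 52.6)^2), 1)

  # two plants separated by far more than the filter support
  f2 <- synfoci:::add_spot(f, 60, 30, 150, 1.4)
  two <- detect_membrane_structures(frame_stack(f2, 100, 0.1), cell, cfg)
  expect_equal(nrow(two), 2L)
})

test_that("preexisting structures are excluded; appearing/moving kept", {
  mk <- function(frame, row, col) tibble::tibble(frame = frame, row = row,
                                                 col = col)
  # stationary from frame 1: excluded
  ser <- mk(1:6, 20, 20)
  ev <- track_and_filter_dynamic(ser, 3, 500, 100)
  expect_equal(nrow(ev$events), 0L)
  # appears at frame 3: included
  ser2 <- mk(3:6, 20, 20)
  ev2 <- track_and_filter_dynamic(ser2, 3, 500, 100)
  expect_equal(nrow(ev2$events), 1L)
  expect_true(ev2$events$appeared)
  # present from frame 1 but moves: net motion 6 px with 2 px/frame steps
  ser3 <- mk(1:4, 20, c(20, 22, 24, 26))
  expect_equal(nrow(track_and_filter_dynamic(ser3, 5, 5000, 100)$events), 1L)
  expect_equal(nrow(track_and_filter_dynamic(ser3, 7, 5000, 100)$events), 0L)
})

test_that("event association equals exhaustive per-point mask lookup", {
  set.seed(23)
  n <- 60
  foci_labels <- matrix(0L, n, n); foci_labels[10:14, 10:14] <- 1L
  foci_labels[40:44, 20:24] <- 2L
  fib <- matrix(FALSE, n, n); fib[30, 5:55] <- TRUE; fib[5:55, 50] <- TRUE
  foci_by_frame <- lapply(1:6, function(t) {
    foci_set(t, foci_labels, tibble::tibble(focus_id = 1:2, row = c(12, 42),
                                            col = c(12, 22), area_px = 25L,
                                            elongation = 1))
  })
  fibers_by_frame <- lapply(1:6, function(t) fiber_mask(t, fib))
  pts <- tibble::tibble(frame = rep(2:6, 8),
                        row = runif(40, 2, n - 2), col = runif(40, 2, n - 2))
  ev <- track_and_filter_dynamic(pts, 3, 100000, 100)
  ev <- associate_events(ev, foci_by_frame, fibers_by_frame)
  # oracle: literal lookup per event point
  for (i in seq_len(nrow(ev$events))) {
    pp <- ev$points[ev$points$event_id == ev$events$event_id[i], ]
    on_f <- any(foci_labels[cbind(pmin(pmax(round(pp$row), 1), n),
                                  pmin(pmax(round(pp$col), 1), n))] > 0)
    on_b <- any(fib[cbind(pmin(pmax(round(pp$row), 1), n),
                          pmin(pmax(round(pp$col), 1), n))])
    want <- if (on_f && on_b) "both" else if (on_f) "foci" else
      if (on_b) "fibers" else "none"
    expect_equal(ev$events$association[i], want)
  }
  # exactly one label per event; label counts partition the events
  expect_true(all(ev$events$association %in%
                    c("foci", "fibers", "both", "none")))
})

test_that("pulling summary percentages and area rates follow the definitions", {
  n <- 60
  foci_labels <- matrix(0L, n, n); foci_labels[10:14, 10:14] <- 1L  # 25 px
  fib <- matrix(FALSE, n, n); fib[30:32, 6:30] <- TRUE              # 75 px
  foci_by_frame <- lapply(1:5, function(t) {
    foci_set(t, foci_labels, tibble::tibble(focus_id = 1L, row = 12,
                                            col = 12, area_px = 25L,
                                            elongation = 1))
  })
  fibers_by_frame <- lapply(1:5, function(t) fiber_mask(t, fib))
  cell <- cell_mask(matrix(TRUE, n, n), 100)
  # 10 appearing events: 3 on the focus, 3 on the fiber, 4 on background
  rows <- c(12, 12, 12, 31, 31, 31, 50, 50, 50, 50)
  cols <- c(12, 13, 11, 10, 15, 20, 5, 15, 25, 35)
  pts <- dplyr::bind_rows(lapply(1:10, function(i) {
    tibble::tibble(frame = c(2L, 3L), row = rows[i], col = cols[i])
  }))
  ev <- associate_events(track_and_filter_dynamic(pts, 3, 500, 100),
                         foci_by_frame, fibers_by_frame)
  s <- summarize_pulling(ev, cell, foci_by_frame, fibers_by_frame)
  expect_equal(s$n_events, 10L)
  expect_equal(s$pct_events_foci, 30)
  expect_equal(s$pct_events_fibers, 30)
  expect_equal(s$pct_events_none, 40)
  # equal counts but the focus covers 1/3 the fiber area -> 3x the rate
  expect_equal(s$rate_per_foci_area / s$rate_per_fiber_area, 3)
})

test_that("planted static blemishes never contribute to summaries", {
  s <- pulling_segmented()
  cfg <- s$cfg
  ser <- detect_membrane_structures(s$scene$dii, s$cell, cfg)
  ev <- track_and_filter_dynamic(ser, cfg$motion_threshold_px,
                                 cfg$link_max_dist_nm,
                                 s$scene$dii$pixel_size_nm)
  truth <- s$scene$truth
  stat_ids <- truth$dii_events$event_id[!truth$dii_events$dynamic]
  sp <- truth$dii_positions[truth$dii_positions$event_id %in% stat_ids, ]
  if (nrow(ev$points) && nrow(sp)) {
    d <- sqrt(outer(ev$points$row, sp$row, "-")^2 +
              outer(ev$points$col, sp$col, "-")^2)
    expect_gt(min(d), 2)
  }
  expect_gt(nrow(sp), 0L)  # blemishes were planted
})
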