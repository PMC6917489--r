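test_that("structure-free noise-free scenes are flat background", {
  p <- small_scene_params(foci_birth_rate_per_um2_per_s = 0,
                          initial_foci_count = 0L, n_fibers = 0L,
                          dii_event_rate_per_frame = 0,
                          dii_static_blemish_count = 0L,
                          poisson_noise = FALSE, read_noise_sd = 0,
                          rng_seed = 2L)
  sc <- generate_scene(p)
  cell <- sc$truth$cell_mask_true
  for (t in c(1L, 15L)) {
    fr <- get_frame(sc$actin, t)
    expect_true(all(fr[cell] == p$background_level))
    expect_true(all(fr[!cell] == p$outside_level))
  }
  expect_equal(nrow(sc$truth$foci_events), 0L)
})

test_that("an immortal immobile focus keeps one center in every frame", {
  p <- small_scene_params(foci_birth_rate_per_um2_per_s = 0,
                          initial_foci_count = 1L,
                          foci_lifetime_mean_s = 1e6,
                          foci_diffusion_um2_per_s = 0, n_fibers = 0L,
                          dii_event_rate_per_frame = 0,
                          dii_static_blemish_count = 0L, rng_seed = 3L)
  sc <- generate_scene(p)
  tp <- sc$truth$foci_positions
  expect_equal(nrow(tp), p$n_frames)
  expect_equal(length(unique(tp$row)), 1L)
  expect_equal(length(unique(tp$col)), 1L)
  expect_true(all(sc$truth$foci_events$recoverable))
})

test_that("scenes are bit-deterministic in their seed", {
  p <- small_scene_params(rng_seed = 6L)
  a <- generate_scene(p)
  b <- generate_scene(p)
  expect_identical(a$actin$pixels, b$actin$pixels)
  expect_identical(a$dii$pixels, b$dii$pixels)
  expect_identical(a$truth$foci_positions, b$truth$foci_positions)
})

test_that("noise-free scenes re-render exactly from ground truth", {
  p <- small_scene_params(poisson_noise = FALSE, read_noise_sd = 0,
                          rng_seed = 9L)
  sc <- generate_scene(p)
  sigma_spot <- p$foci_width_nm / (2.355 * p$pixel_size_nm)
  sigma_fib <- p$fiber_width_nm / (2.355 * p$pixel_size_nm)
  cell <- sc$truth$cell_mask_true
  base <- matrix(p$outside_level, p$image_size_px, p$image_size_px)
  base[cell] <- p$background_level
  fb <- sc$truth$fiber_segments
  for (i in seq_len(nrow(fb))) {
    base <- synfoci:::add_ridge(base, fb$r0[i], fb$c0[i], fb$r1[i], fb$c1[i],
                                p$fiber_amplitude, sigma_fib)
  }
  for (t in c(1L, 10L, 30L)) {
    fr <- base
    pp <- sc$truth$foci_positions[sc$truth$foci_positions$frame == t, ]
    for (q in seq_len(nrow(pp))) {
      fr <- synfoci:::add_spot(fr, pp$row[q], pp$col[q], p$foci_amplitude,
                               sigma_spot)
    }
    expect_equal(get_frame(sc$actin, t), fr, tolerance = 0)
  }
})

test_that("planted foci counts follow the Poisson birth process", {
  # small scenes, rendering skipped would be ideal; keep them tiny instead
  p0 <- scene_params(image_size_px = 64L, n_frames = 10L,
                     cell_radius_um = 2.5, n_fibers = 0L,
                     foci_birth_rate_per_um2_per_s = 0.2,
                     dii_event_rate_per_frame = 0,
                     dii_static_blemish_count = 0L, rng_seed = 1L)
  area <- pi * 2.5^2
  counts <- vapply(1:60, function(s) {
    p <- scene_params(image_size_px = 64L, n_frames = 10L,
                      cell_radius_um = 2.5, n_fibers = 0L,
                      foci_birth_rate_per_um2_per_s = 0.2,
                      dii_event_rate_per_frame = 0,
                      dii_static_blemish_count = 0L, rng_seed = s)
    nrow(generate_scene(p)$truth$foci_events)
  }, 0)
  # expected: steady-state pool + births over (n_frames - 1) intervals,
  # with the disc area quantized to pixels
  area_px <- sum(generate_scene(p0)$truth$cell_mask_true) * 0.01
  lambda <- 0.2 * area_px * (3 + 9 * 0.1)
  se <- sqrt(lambda / 60)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
})

test_that("the fixture suite is deterministic and bookkeeps ground truth", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  render_fixture_suite(d1, seed = 1L)
  render_fixture_suite(d2, seed = 1L)
  for (nm in c("empty", "single_focus", "foci_fibers", "pulling",
               "fibers_only", "foci_only")) {
    expect_true(file.exists(file.path(d1, nm, "actin.tif")))
    expect_identical(unname(tools::md5sum(file.path(d1, nm, "actin.tif"))),
                     unname(tools::md5sum(file.path(d2, nm, "actin.tif"))))
  }
  # Arp2/3-inhibited-like fixture has no planted foci
  fo <- read.csv(file.path(d1, "fibers_only", "foci_events.csv"))
  expect_equal(nrow(fo), 0L)
  # formin-inhibited-like fixture has no fibers
  fs <- read.csv(file.path(d1, "foci_only", "fiber_segments.csv"))
  expect_equal(nrow(fs), 0L)
  # ground-truth CSV rows equal the in-memory records
  sc <- generate_scene(small_scene_params(rng_seed = 3L))  # foci_fibers seed
  ev_csv <- read.csv(file.path(d1, "foci_fibers", "foci_events.csv"))
  expect_equal(nrow(ev_csv), nrow(sc$truth$foci_events))
})
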