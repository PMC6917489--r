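test_that("8-connectivity joins diagonals; labels are deterministic", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE; m[5, 5] <- TRUE
  expect_equal(max(label_components(m, 8L)), 2L)
  expect_equal(max(label_components(m, 4L)), 3L)
  l1 <- label_components(m, 8L)
  expect_identical(l1, label_components(m, 8L))
  expect_equal(l1[2, 2], 1L)  # raster order
})

test_that("component statistics match hand-computed moments", {
  m <- matrix(FALSE, 10, 12)
  m[3:5, 4:6] <- TRUE                 # 3x3 square
  st <- component_stats(label_components(m))
  expect_equal(st$area_px, 9L)
  expect_equal(st$row, 4); expect_equal(st$col, 5)
  # square: equal eigenvalues -> elongation 1
  expect_equal(st$elongation, 1, tolerance = 1e-12)

  # weighted centroid pulls toward the bright pixel
  w <- matrix(1, 10, 12); w[5, 6] <- 10
  stw <- component_stats(label_components(m), weights = w)
  expect_gt(stw$row, 4); expect_gt(stw$col, 5)
})

test_that("relative threshold references the raw frame mean over the cell", {
  # 5x5 toy frame: cell mean 2.0, fraction 1.5 -> keep response >= 3.0
  frame <- matrix(2, 5, 5)
  resp <- response_map(matrix(c(rep(1, 10), rep(3, 10), rep(5, 5)), 5, 5),
                       "foci", 325)
  cell <- cell_mask(matrix(TRUE, 5, 5), 100)
  kept <- threshold_relative(resp, frame, cell, 1.5)
  expect_identical(kept, resp$values >= 3.0)
  expect_equal(sum(kept), 15L)

  # uniform frame: response equals the mean, fraction 0.5 keeps whole cell
  u <- matrix(4, 5, 5)
  ru <- response_map(u, "foci", 325)
  expect_true(all(threshold_relative(ru, u, cell, 0.5)))
  # threshold above max response gives an empty mask
  expect_false(any(threshold_relative(ru, u, cell, 2)))
  expect_error(threshold_relative(ru, u, cell_mask(matrix(FALSE, 5, 5), 100),
                                  0.5), "empty")
})

test_that("foci detection keeps compact blobs and rejects ridges and ties", {
  cfg <- pipeline_config()
  n <- 32
  mk_resp <- function(v) response_map(v, "foci", 325)
  mk_fib <- function(v) response_map(v, "fiber", 325)

  disk <- matrix(0, n, n)
  co <- seq_len(n)
  disk[outer((co - 16)^2, (co - 16)^2, "+") <= 9] <- 5
  fs <- detect_foci(disk > 0, mk_resp(disk), mk_fib(matrix(1, n, n)), cfg)
  expect_equal(nrow(fs$table), 1L)
  expect_equal(fs$table$row, 16, tolerance = 0.01)

  # fiber response dominating everywhere -> no foci
  fs2 <- detect_foci(disk > 0, mk_resp(disk), mk_fib(disk + 1), cfg)
  expect_equal(nrow(fs2$table), 0L)
  # equality is resolved as fiber ("exceeded" is strict)
  fs3 <- detect_foci(disk > 0, mk_resp(disk), mk_fib(disk), cfg)
  expect_equal(nrow(fs3$table), 0L)
})

test_that("elongation filter removes lines but keeps rectangles", {
  cfg <- pipeline_config()  # max_elongation 3
  line <- matrix(0, 30, 30); line[15, 5:24] <- 5       # 1 x 20 line
  rect <- matrix(0, 30, 30); rect[10:14, 10:13] <- 5   # 5 x 4 rectangle
  fib <- response_map(matrix(0, 30, 30), "fiber", 325)

  # second-moment oracle, computed from coordinates directly
  elong <- function(m) {
    px <- which(m > 0, arr.ind = TRUE)
    v <- eigen(cov(px) * (nrow(px) - 1) / nrow(px) + diag(2) / 12)$values
    sqrt(v[1] / v[2])
  }
  expect_gt(elong(line), cfg$max_elongation)
  expect_lt(elong(rect), cfg$max_elongation)

  got_line <- detect_foci(line > 0, response_map(line, "foci", 325), fib, cfg)
  got_rect <- detect_foci(rect > 0, response_map(rect, "foci", 325), fib, cfg)
  expect_equal(nrow(got_line$table), 0L)
  expect_equal(nrow(got_rect$table), 1L)
  expect_equal(got_rect$table$elongation, elong(rect), tolerance = 1e-9)
})

test_that("fiber mask excludes foci pixels and respects the cell", {
  s <- small_segmented()
  for (t in c(1L, 15L, 30L)) {
    foci_px <- s$seg$foci_by_frame[[t]]$labels > 0L
    fib_px <- s$seg$fibers_by_frame[[t]]$mask
    expect_equal(sum(foci_px & fib_px), 0L)
    expect_true(all(s$cell$mask[foci_px]))
    expect_true(all(s$cell$mask[fib_px]))
  }
})

test_that("intensity scaling leaves foci and fiber masks unchanged", {
  s <- small_segmented()
  fr <- get_frame(s$scene$actin, 10L)
  cfg <- s$cfg
  run <- function(f) {
    fo <- enhance_foci(f, cfg$foci_scale_nm, 100)
    fi <- enhance_fibers(f, cfg$fiber_scale_nm, 100, cfg$n_orientations)
    fm <- threshold_relative(fo, f, s$cell, cfg$foci_threshold_fraction)
    foci <- detect_foci(fm, fo, fi, cfg)
    fib <- detect_fibers(fi, f, s$cell, foci, cfg$fiber_threshold_fraction)
    list(resp = fo$values, foci = foci$labels, fib = fib$mask)
  }
  a <- run(fr)
  b <- run(fr * 3.7)
  expect_equal(b$resp, a$resp * 3.7, tolerance = 1e-12)
  expect_identical(a$foci, b$foci)
  expect_identical(a$fib, b$fib)
})

test_that("detection masks equal the pixelwise comparison oracle", {
  s <- small_segmented()
  cfg <- s$cfg
  fr <- get_frame(s$scene$actin, 12L)
  fo <- enhance_foci(fr, cfg$foci_scale_nm, 100)
  fi <- enhance_fibers(fr, cfg$fiber_scale_nm, 100, cfg$n_orientations)
  fm <- threshold_relative(fo, fr, s$cell, cfg$foci_threshold_fraction)
  got <- detect_foci(fm, fo, fi, cfg)
  # oracle: literal pixelwise definition of the candidate set
  cand_oracle <- s$cell$mask &
    (fo$values >= cfg$foci_threshold_fraction * mean(fr[s$cell$mask])) &
    (fo$values > fi$values)
  expect_identical(fm & (fo$values > fi$values), cand_oracle)
  # every retained focus pixel is a candidate pixel
  expect_true(all(cand_oracle[got$labels > 0L]))
})
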