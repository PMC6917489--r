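test_that("enrichment is 1 for uniform signal and 1/a for a concentrated one", {
  cell <- cell_mask(matrix(TRUE, 20, 20), 100)
  sig <- matrix(4, 20, 20)
  m <- matrix(FALSE, 20, 20); m[3:7, 3:7] <- TRUE
  expect_equal(enrichment(sig, m, cell)$enrichment, 1)

  # all signal inside a structure occupying fraction a of the cell
  a <- sum(m) / sum(cell$mask)
  sig2 <- matrix(0, 20, 20); sig2[m] <- 9
  expect_equal(enrichment(sig2, m, cell)$enrichment, 1 / a)

  expect_warning(res <- enrichment(sig, matrix(FALSE, 20, 20), cell), "empty")
  expect_true(is.nan(res$enrichment))
  expect_error(enrichment(matrix(0, 20, 20), m, cell), "zero mean")
})

test_that("toy-frame enrichment equals hand-computed means", {
  sig <- matrix(seq_len(64), 8, 8)
  cell <- cell_mask(matrix(TRUE, 8, 8), 100)
  m <- matrix(FALSE, 8, 8); m[1:2, 1:2] <- TRUE
  # hand: structure pixels are values 1,2,9,10 -> mean 5.5; cell mean 32.5
  expect_equal(enrichment(sig, m, cell)$enrichment, 5.5 / 32.5)
})

test_that("area-weighted enrichment over a partition sums to one", {
  s <- small_segmented()
  fr <- get_frame(s$scene$actin, 7L)
  foci_px <- s$seg$foci_by_frame[[7L]]$labels > 0L
  fib_px <- s$seg$fibers_by_frame[[7L]]$mask
  rest <- s$cell$mask & !foci_px & !fib_px
  total <- 0
  for (m in list(foci_px, fib_px, rest)) {
    if (!any(m)) next
    e <- enrichment(fr, m, s$cell)$enrichment
    total <- total + e * sum(m) / sum(s$cell$mask)
  }
  expect_equal(total, 1, tolerance = 1e-9)
})

test_that("center-overlap fractions match brute-force containment", {
  labels <- matrix(0L, 33, 33)
  centers <- cbind(seq(3, 30, by = 3), seq(3, 30, by = 3))
  for (i in seq_len(10)) {
    labels[centers[i, 1] + (-1:1), centers[i, 2] + (-1:0)] <- i
  }
  pts <- tibble::tibble(row = centers[1:3, 1], col = centers[1:3, 2])
  expect_equal(coloc_fraction(labels, pts, "regions"), 0.3)
  expect_equal(coloc_fraction(labels, pts, "points"), 1)
  far <- tibble::tibble(row = c(1, 1), col = c(15, 25))
  expect_equal(coloc_fraction(labels, far, "regions"), 0)
  expect_equal(coloc_fraction(labels, far, "points"), 0)
  # every region containing a center
  all_pts <- tibble::tibble(row = centers[, 1], col = centers[, 2])
  expect_equal(coloc_fraction(labels, all_pts, "regions"), 1)
  expect_warning(v <- coloc_fraction(matrix(0L, 5, 5), pts, "regions"), "no regions")
  expect_true(is.nan(v))
})

test_that("colocalization is invariant under common translation", {
  labels <- matrix(0L, 40, 40)
  labels[5:8, 5:8] <- 1L; labels[20:23, 11:14] <- 2L
  pts <- tibble::tibble(row = c(6.2, 30.0), col = c(6.8, 30.0))
  base_r <- coloc_fraction(labels, pts, "regions")
  base_p <- coloc_fraction(labels, pts, "points")
  sh <- matrix(0L, 40, 40)
  sh[5:8 + 9, 5:8 + 7] <- 1L; sh[20:23 + 9, 11:14 + 7] <- 2L
  pts2 <- dplyr::mutate(pts, row = row + 9, col = col + 7)
  expect_equal(coloc_fraction(sh, pts2, "regions"), base_r)
  expect_equal(coloc_fraction(sh, pts2, "points"), base_p)
})

test_that("randomization null uses the requested runs and is reproducible", {
  set.seed(NULL)
  cell <- cell_mask(matrix(TRUE, 40, 40), 100)
  labels <- matrix(0L, 40, 40); labels[10:19, 10:19] <- 1L
  pts <- tibble::tibble(row = runif(8, 2, 39), col = runif(8, 2, 39),
                        radius_px = 1)
  r1 <- randomized_coloc(labels, pts, cell, n_randomizations = 10L,
                         rng_seed = 5L)
  r2 <- randomized_coloc(labels, pts, cell, n_randomizations = 10L,
                         rng_seed = 5L)
  expect_identical(r1, r2)
  expect_equal(r1$n_randomizations, 10L)

  # regions covering the whole cell: randomized fraction is 1 regardless
  full <- matrix(1L, 40, 40)
  rf <- randomized_coloc(full, pts, cell, 5L, 2L)
  expect_equal(rf$random_fraction_points_in_regions, 1)
})

test_that("randomized point-in-region fraction converges to the area fraction", {
  cell <- cell_mask(matrix(TRUE, 50, 50), 100)
  labels <- matrix(0L, 50, 50)
  labels[6:15, 6:25] <- 1L; labels[30:44, 20:39] <- 2L
  a <- sum(labels > 0) / sum(cell$mask)
  n_pts <- 12L
  pts <- tibble::tibble(row = rep(25, n_pts), col = rep(25, n_pts),
                        radius_px = 0)
  n_runs <- 1000L
  res <- randomized_coloc(labels, pts, cell, n_runs, rng_seed = 8L)
  # Monte-Carlo SE of the mean of n_runs x n_pts Bernoulli(a) draws
  se <- sqrt(a * (1 - a) / (n_runs * n_pts))
  expect_lt(abs(res$random_fraction_points_in_regions - a), 3 * se)
})

test_that("infeasible randomized placement errors with the cell id", {
  cell <- cell_mask(matrix(TRUE, 10, 10), 100, cell_id = 7L)
  labels <- matrix(0L, 10, 10); labels[5, 5] <- 1L
  pts <- tibble::tibble(row = rep(5, 4), col = rep(5, 4), radius_px = 20)
  expect_error(randomized_coloc(labels, pts, cell, 2L, 1L), "cell 7")
})
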