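#' Gaussian spot kernel
#'
#' Isotropic, unit-sum Gaussian kernel. The quoted physical scale is the
#' kernel's full width at half maximum, so `sigma = scale_nm / (2.355 *
#' pixel_size_nm)`. The kernel radius is `max(1, ceiling(3 * sigma))`.
#'
#' @param sigma_px Gaussian sigma in pixels.
#' @return odd-sized numeric matrix summing to 1.
#' @keywords internal
gaussian_kernel <- function(sigma_px) {
  r <- max(1L, ceiling(3 * sigma_px))
  g <- exp(-(-r:r)^2 / (2 * sigma_px^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Oriented anisotropic Gaussian (ridge) kernel
#'
#' @param sigma_long sigma along the line, px.
#' @param sigma_short sigma across the line, px.
#' @param theta_deg line orientation, degrees counter-clockwise from the
#'   column (x) axis.
#' @return odd-sized numeric matrix summing to 1.
#' @keywords internal
line_kernel <- function(sigma_long, sigma_short, theta_deg) {
  r <- max(1L, ceiling(3 * sigma_long))
  th <- theta_deg * pi / 180
  # grid: rows increase downwards; use (x = col, y = -row) so theta is CCW
  xs <- matrix(rep(-r:r, each = 2 * r + 1), 2 * r + 1)
  ys <- -matrix(rep(-r:r, times = 2 * r + 1), 2 * r + 1)
  u <- xs * cos(th) + ys * sin(th)    # along-line coordinate
  v <- -xs * sin(th) + ys * cos(th)   # across-line coordinate
  k <- exp(-u^2 / (2 * sigma_long^2) - v^2 / (2 * sigma_short^2))
  k / sum(k)
}

# mirror-reflected index vector covering positions (1-p)..(n+p)
mirror_idx <- function(n, p) {
  cyc <- c(seq_len(n), rev(seq_len(n)))
  ((seq.int(1 - p, n + p) - 1) %% (2 * n)) + 1 -> pos
  cyc[pos]
}

#' 2-D convolution with mirror-reflected boundaries
#'
#' FFT convolution (via EBImage) of a frame with an odd-sized kernel, with
#' the image border handled by mirror reflection. For kernels symmetric under
#' 180-degree rotation (all kernels used here) convolution and correlation
#' coincide.
#'
#' @param frame numeric matrix.
#' @param kernel odd-sized numeric matrix.
#' @return numeric matrix of the same shape as `frame`.
#' @export
convolve_reflect <- function(frame, kernel) {
  stopifnot(is.matrix(frame), is.matrix(kernel))
  kd <- dim(kernel)
  if (any(kd %% 2L == 0L)) stop("kernel dimensions must be odd")
  pr <- (kd[1] - 1L) %/% 2L
  pc <- (kd[2] - 1L) %/% 2L
  padded <- frame[mirror_idx(nrow(frame), pr), mirror_idx(ncol(frame), pc),
                  drop = FALSE]
  out <- EBImage::filter2(padded, kernel, boundary = "circular")
  out[pr + seq_len(nrow(frame)), pc + seq_len(ncol(frame)), drop = FALSE]
}

#' Response-map container
#' @param values numeric matrix, same shape as the input frame.
#' @param kind `"foci"` or `"fiber"`.
#' @param scale_nm filter scale, nm.
#' @return object of class `response_map`.
#' @export
response_map <- function(values, kind = c("foci", "fiber"), scale_nm) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values), all(is.finite(values)))
  structure(list(values = values, kind = kind, scale_nm = scale_nm),
            class = "response_map")
}

#' Enhance actin foci by matched Gaussian convolution
#'
#' Convolves the frame with a unit-sum isotropic Gaussian whose FWHM equals
#' `scale_nm` (325 nm for primary B cells, 450 nm for Ramos cells).
#' Boundaries are mirror-reflected. Because the kernel sums to 1, a uniform
#' image is mapped to itself.
#'
#' @param frame numeric matrix (one movie frame).
#' @param scale_nm filter FWHM, nm.
#' @param pixel_size_nm pixel edge length, nm.
#' @return a [response_map] of kind `"foci"`.
#' @export
enhance_foci <- function(frame, scale_nm, pixel_size_nm) {
  stopifnot(scale_nm > 0, pixel_size_nm > 0)
  sigma <- scale_nm / (2.355 * pixel_size_nm)
  if (sigma < 0.5) {
    warning("foci filter scale is below one pixel; kernel degenerates ",
            "toward the identity")
  }
  response_map(convolve_reflect(frame, gaussian_kernel(sigma)),
               "foci", scale_nm)
}

#' Enhance actin fibers by oriented ridge filtering
#'
#' Takes the pixelwise maximum over `n_orientations` unit-sum anisotropic
#' Gaussian line kernels at angles `k * 180 / n_orientations` degrees
#' (k = 0, ..., n_orientations - 1); the default 10 orientations correspond
#' to 18-degree increments, covering filaments of all orientations. The
#' transverse scale of the ridge is `scale_nm`; along the ridge the kernel
#' extends with sigma `long_factor` times the matched spot sigma, across it
#' `short_factor` times (defaults 3 and 0.5). The long axis must extend well
#' beyond the spot scale: it sets the margin by which the spot filter beats
#' the ridge filter on round structures, and hence how robustly the
#' spot-vs-ridge competition classifies them under noise.
#'
#' @inheritParams enhance_foci
#' @param n_orientations number of kernel orientations over 180 degrees.
#' @param long_factor,short_factor anisotropy of the ridge kernel relative to
#'   the matched spot sigma.
#' @return a [response_map] of kind `"fiber"`.
#' @export
enhance_fibers <- function(frame, scale_nm, pixel_size_nm,
                           n_orientations = 10L,
                           long_factor = 3, short_factor = 0.5) {
  stopifnot(scale_nm > 0, pixel_size_nm > 0, n_orientations >= 2L)
  sigma <- scale_nm / (2.355 * pixel_size_nm)
  if (sigma * short_factor < 0.25) {
    warning("fiber filter transverse scale is far below one pixel")
  }
  angles <- (seq_len(n_orientations) - 1L) * 180 / n_orientations
  out <- NULL
  for (a in angles) {
    k <- line_kernel(sigma * long_factor, sigma * short_factor, a)
    resp <- convolve_reflect(frame, k)
    out <- if (is.null(out)) resp else pmax(out, resp)
  }
  response_map(out, "fiber", scale_nm)
}
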