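# Feature 3: texture of the monitor image around the gaze point. A bank of
# real-part Gabor wavelets (K orientations x P+1 amplitude scales) is applied
# to a gaze-centered ROI and the mean absolute response over all kernels and
# ROI pixels is the raw feature; textured targets score high, blank regions
# score (exactly) zero because each kernel is DC-removed.

#' Gabor filter-bank parameters
#'
#' @param sigma_x,sigma_y spatial standard deviations, pixels.
#' @param radial_freq radial frequency `W` of the sinusoid, cycles/pixel.
#' @param n_orientations number of orientations `K` (`theta = n*pi/K`).
#' @param n_scales number of scales `P + 1` (amplitude factor `a^-m`).
#' @param scale_base scale base `a > 1`.
#' @return list of validated parameters.
#' @export
gabor_params <- function(sigma_x = 2, sigma_y = 2, radial_freq = 0.25,
                         n_orientations = 4, n_scales = 4, scale_base = sqrt(2)) {
  stopifnot(n_orientations >= 1, n_scales >= 1, scale_base > 1,
            sigma_x > 0, sigma_y > 0)
  list(sigma_x = sigma_x, sigma_y = sigma_y, radial_freq = radial_freq,
       n_orientations = n_orientations, n_scales = n_scales,
       scale_base = scale_base)
}

#' One real Gabor wavelet kernel
#'
#' Samples `a^-m * Re{g(x', y')}` on the integer grid, where `g` is the mother
#' Gabor function
#' `g(x, y) = (1 / (2 pi sx sy)) exp(-(x^2/sx^2 + y^2/sy^2) / 2) * exp(2 pi i W x)`
#' and `(x', y')` are the coordinates rotated by `theta = n pi / K`
#' (`x' = x cos + y sin`, `y' = -x sin + y cos`). Only the real (cosine) part
#' is used. Each kernel is DC-removed (its mean subtracted) so that constant
#' image regions respond exactly zero.
#'
#' @param params from [gabor_params()].
#' @param m scale index, `0 .. P`.
#' @param n orientation index, `0 .. K-1`.
#' @param support kernel half-size in pixels; the kernel is
#'   `(2*support+1)` square. Default `ceiling(4 * max(sigma))`.
#' @param dc_remove subtract the kernel mean (default `TRUE`).
#' @return numeric matrix (row = y, col = x).
#' @export
gabor_kernel <- function(params, m, n, support = NULL, dc_remove = TRUE) {
  stopifnot(m >= 0, m <= params$n_scales - 1, n >= 0, n < params$n_orientations)
  if (is.null(support)) support <- ceiling(4 * max(params$sigma_x, params$sigma_y))
  theta <- n * pi / params$n_orientations
  d <- -support:support
  xs <- matrix(d, 2 * support + 1, 2 * support + 1, byrow = TRUE)
  ys <- matrix(d, 2 * support + 1, 2 * support + 1)
  xr <- xs * cos(theta) + ys * sin(theta)
  yr <- -xs * sin(theta) + ys * cos(theta)
  env <- exp(-0.5 * (xr^2 / params$sigma_x^2 + yr^2 / params$sigma_y^2)) /
    (2 * pi * params$sigma_x * params$sigma_y)
  k <- params$scale_base^(-m) * env * cos(2 * pi * params$radial_freq * xr)
  if (dc_remove) k <- k - mean(k)
  k
}

#' Build the full Gabor filter bank
#'
#' All `K * (P + 1)` kernels; with the defaults (`K = 4`, `P = 3`), 16.
#'
#' @inheritParams gabor_kernel
#' @return a `gabor_bank`: list of kernels with `scale`/`orientation` labels.
#' @export
build_bank <- function(params = gabor_params(), support = NULL, dc_remove = TRUE) {
  grid <- expand.grid(m = 0:(params$n_scales - 1),
                      n = 0:(params$n_orientations - 1))
  kernels <- purrr::map2(grid$m, grid$n, function(m, n) {
    structure(gabor_kernel(params, m, n, support, dc_remove), scale = m, orientation = n)
  })
  structure(kernels, class = "gabor_bank", params = params)
}

#' Raw Feature 3: mean Gabor magnitude inside a gaze-centered ROI
#'
#' Crops the ROI (clipped to the image), convolves it with every kernel of the
#' bank (reflect padding), and returns the mean absolute response over all
#' kernels and ROI pixels.
#'
#' @param monitor_image numeric matrix (grayscale screenshot); 3-channel
#'   arrays are converted to luminance.
#' @param center gaze point `c(x, y)` in monitor pixels, 0-based.
#' @param bank from [build_bank()].
#' @param half_width,half_height ROI half-extents in pixels (101 x 101 ROI by
#'   default).
#' @return the mean magnitude, `>= 0`.
#' @export
texture_score <- function(monitor_image, center, bank = build_bank(),
                          half_width = 50, half_height = 50) {
  if (length(dim(monitor_image)) == 3L) {
    monitor_image <- 0.299 * monitor_image[, , 1] + 0.587 * monitor_image[, , 2] +
      0.114 * monitor_image[, , 3]
  }
  nr <- nrow(monitor_image); nc <- ncol(monitor_image)
  r0 <- max(1L, round(center[[2]]) - half_height + 1L)
  r1 <- min(nr, round(center[[2]]) + half_height + 1L)
  c0 <- max(1L, round(center[[1]]) - half_width + 1L)
  c1 <- min(nc, round(center[[1]]) + half_width + 1L)
  if (r0 > r1 || c0 > c1) abort("ROI off-screen")
  roi <- monitor_image[r0:r1, c0:c1, drop = FALSE]
  resp <- vapply(bank, function(k) mean(abs(conv2_reflect(roi, k))), numeric(1))
  mean(resp)
}
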