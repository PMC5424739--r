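# Pupil and glint segmentation: histogram binarization -> morphological
# cleaning -> circular Hough rough estimate -> Chan-Vese refinement restricted
# to an adaptive mask around the rough circle -> geometric centers.

#' Binarize dark regions of an eye frame
#'
#' Thresholds the intensity image to a logical mask of the dark pixels
#' (candidate pupil). With `threshold = "auto"` the cut is chosen by Otsu's
#' inter-class-variance criterion on the intensity histogram.
#'
#' @param frame numeric matrix, intensities in `[0, 255]`.
#' @param threshold a fixed intensity in `[0, 255]`, or `"auto"`.
#' @return logical matrix, `TRUE` where `frame < threshold`.
#' @export
binarize_dark_regions <- function(frame, threshold = "auto") {
  if (length(frame) == 0L) abort("frame is empty")
  if (identical(threshold, "auto")) {
    if (length(unique(as.vector(frame))) < 2L) {
      abort("degenerate histogram: image has a single intensity level")
    }
    threshold <- 255 * EBImage::otsu(as_ebi(frame / 255), range = c(0, 1))
  }
  stopifnot_scalar_number(threshold, "threshold")
  frame < threshold
}

#' Remove speckle noise from a binary mask
#'
#' Morphological opening with a disc structuring element, then a square median
#' (majority) filter, then retention of the largest 8-connected component.
#'
#' @param mask logical matrix.
#' @param open_radius disc radius of the opening element, pixels.
#' @param median_size side of the median window, odd pixels.
#' @return logical matrix.
#' @export
clean_binary <- function(mask, open_radius = 2, median_size = 3) {
  if (!any(mask)) return(mask & FALSE)
  m <- mask * 1
  if (open_radius > 0) {
    m <- ebi_data(EBImage::opening(as_ebi(m), EBImage::makeBrush(2 * open_radius + 1, "disc")))
  }
  m <- m > 0.5
  if (median_size >= 3) {
    # median of a binary image = neighborhood majority (out-of-bounds counts
    # as background)
    cnt <- box_count(m, median_size)
    m <- cnt > median_size^2 / 2
  }
  largest_component(m)
}

#' Detect the strongest circle by circular Hough transform
#'
#' Builds an accumulator by voting from the boundary pixels of `mask_or_edges`
#' over integer radii in `radius_range` (each boundary pixel votes for all
#' centers at distance `r`), and returns the highest-vote circle. Ties are
#' broken toward the smaller radius, then the first accumulator cell in
#' column-major order.
#'
#' @param mask_or_edges logical matrix; filled regions are reduced to their
#'   boundary before voting, a thin edge map is used as is.
#' @param radius_range integer `c(rmin, rmax)`, `rmin >= 2`.
#' @param min_votes vote floor below which no circle is reported.
#' @return a `circle_estimate`: list with `center` (0-based `c(x, y)`),
#'   `radius`, and `score` (votes).
#' @export
detect_circle_cht <- function(mask_or_edges, radius_range, min_votes = 6) {
  stopifnot(length(radius_range) == 2L, radius_range[1] >= 2,
            radius_range[2] > radius_range[1])
  m <- mask_or_edges != 0
  if (!any(m)) abort("no circle found: empty input")
  eroded <- ebi_data(EBImage::erode(as_ebi(m * 1), EBImage::makeBrush(3, "box"))) > 0.5
  edges <- (m & !eroded) * 1

  nr <- nrow(edges); nc <- ncol(edges)
  epix <- which(edges > 0)
  er <- (epix - 1L) %% nr; ec <- (epix - 1L) %/% nr   # 0-based row/col
  best <- list(score = -Inf)
  for (r in seq(radius_range[1], radius_range[2])) {
    ring <- which(ring_kernel(r) > 0)
    dr <- (ring - 1L) %% (2L * r + 1L) - r
    dc <- (ring - 1L) %/% (2L * r + 1L) - r
    # every edge pixel votes for all centers on its ring
    rows <- rep(er, times = length(dr)) + rep(dr, each = length(er))
    cols <- rep(ec, times = length(dc)) + rep(dc, each = length(ec))
    keep <- rows >= 0L & rows < nr & cols >= 0L & cols < nc
    votes <- tabulate(rows[keep] + nr * cols[keep] + 1L, nbins = nr * nc)
    i <- which.max(votes)
    if (votes[i] > best$score) {
      best <- list(center = c(x = (i - 1L) %/% nr, y = (i - 1L) %% nr),
                   radius = r, score = votes[i])
    }
  }
  if (best$score < min_votes) abort("no circle found: vote maximum below floor")
  structure(best, class = "circle_estimate")
}

# Annulus kernel: 1 where the offset length rounds to r.
ring_kernel <- function(r) {
  d <- -r:r
  dist <- sqrt(outer(d^2, d^2, "+"))
  (dist >= r - 0.5 & dist < r + 0.5) * 1
}

# count of TRUE cells in the size x size window around each cell
# (out-of-bounds counted as FALSE), via a summed-area table
box_count <- function(mask, size) {
  h <- (size - 1L) %/% 2L
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(0L, nr + 2L * h, nc + 2L * h)
  p[(h + 1):(h + nr), (h + 1):(h + nc)] <- mask
  sat <- apply(apply(p, 2, cumsum), 1, cumsum)  # transposed SAT
  sat <- rbind(0, cbind(0, t(sat)))
  i0 <- seq_len(nr); j0 <- seq_len(nc)
  sat[i0 + 2L * h + 1L, j0 + 2L * h + 1L, drop = FALSE] -
    sat[i0, j0 + 2L * h + 1L, drop = FALSE] -
    sat[i0 + 2L * h + 1L, j0, drop = FALSE] + sat[i0, j0, drop = FALSE]
}

#' Refine a region boundary with an adaptive-mask Chan-Vese contour
#'
#' Minimizes the two-phase piecewise-constant segmentation energy
#' `mu * Length(C) + lambda_in * sum_in (u - c_in)^2 +
#'  lambda_out * sum_out (u - c_out)^2`
#' over labellings of the pixels inside an adaptive mask (a disc centered on
#' the seed circle with radius `mask_margin` times the seed radius; pixels
#' outside the mask are fixed to the outer phase). Intensities are normalized
#' to `[0, 1]`; `Length(C)` is the count of 4-adjacent label discordances.
#' The labelling is initialized from the seed circle and updated by
#' checkerboard sweeps of single-pixel flips, each accepted only if it strictly
#' lowers the energy, so the energy is non-increasing across iterations by
#' construction.
#'
#' @param frame numeric matrix in `[0, 255]`.
#' @param seed a `circle_estimate` (or list with `center`, `radius`).
#' @param mask_margin mask radius as a multiple of the seed radius.
#' @param mask_min_radius lower bound on the mask radius in pixels, so that a
#'   rough estimate that undershoots the radius still leaves the contour room
#'   to grow back (the mask must contain the region plus a background ring).
#' @param mu curve-length weight (on the normalized intensity scale).
#' @param lambda_in,lambda_out inner/outer fit weights.
#' @param max_iter maximum number of full sweeps.
#' @param conv_tol stop when fewer than this fraction of mask pixels flip.
#' @param fill_holes fill interior holes of the final region (used for the
#'   pupil, whose interior may contain the excluded bright glint).
#' @return a `region_boundary`: list with `mask` (logical, frame-sized),
#'   `contour` (ordered 0-based `(x, y)` boundary pixels), `area` (pixels),
#'   `c_in`, `c_out` (converged region means on the 0-255 scale), and an
#'   `energy` attribute with the per-iteration energy trace.
#' @export
refine_boundary_chan_vese <- function(frame, seed, mask_margin = 1.5,
                                      mu = 0.05, lambda_in = 1, lambda_out = 1,
                                      max_iter = 200, conv_tol = 0.001,
                                      fill_holes = FALSE, mask_min_radius = 0) {
  stopifnot(max_iter >= 1)
  u_full <- frame / 255
  cx <- seed$center[[1]]; cy <- seed$center[[2]]; r <- seed$radius
  rm <- max(mask_margin * r, mask_min_radius)
  nr <- nrow(frame); nc <- ncol(frame)

  # bounding box of the adaptive mask, clipped to the frame
  r0 <- max(1L, floor(cy - rm) + 1L); r1 <- min(nr, ceiling(cy + rm) + 1L)
  c0 <- max(1L, floor(cx - rm) + 1L); c1 <- min(nc, ceiling(cx + rm) + 1L)
  if (r0 > r1 || c0 > c1) abort("seed circle does not intersect the frame")
  u <- u_full[r0:r1, c0:c1, drop = FALSE]
  lx <- cx - (c0 - 1); ly <- cy - (r0 - 1)   # seed center in local 0-based coords
  M <- disk_mask(nrow(u), ncol(u), lx, ly, rm)
  inside <- disk_mask(nrow(u), ncol(u), lx, ly, r) & M
  if (!any(inside) || all(inside == M)) abort("segmentation collapsed: bad seed")

  parity <- (row(u) + col(u)) %% 2
  n_mask <- sum(M)
  energies <- numeric(0)
  for (it in seq_len(max_iter)) {
    flips <- 0L
    for (k in 0:1) {
      cin <- mean(u[inside]); cout <- mean(u[M & !inside])
      n_in <- shift_sum(inside)
      d_data <- ifelse(inside,
                       lambda_out * (u - cout)^2 - lambda_in * (u - cin)^2,
                       lambda_in * (u - cin)^2 - lambda_out * (u - cout)^2)
      d_len <- ifelse(inside, 2 * n_in - 4, 4 - 2 * n_in)
      flip <- M & parity == k & (d_data + mu * d_len < -1e-12)
      inside <- xor(inside, flip)
      flips <- flips + sum(flip)
      if (!any(inside) || all(inside[M])) abort("segmentation collapsed")
    }
    cin <- mean(u[inside]); cout <- mean(u[M & !inside])
    energies <- c(energies, chan_vese_energy(u, inside, M, mu, lambda_in, lambda_out, cin, cout))
    if (flips < conv_tol * n_mask) break
  }

  full <- matrix(FALSE, nr, nc)
  full[r0:r1, c0:c1] <- inside
  full <- largest_component(full)
  if (fill_holes) full <- ebi_data(EBImage::fillHull(as_ebi(full * 1))) > 0.5
  oc <- EBImage::ocontour(as_ebi(full * 1))[[1]]
  structure(
    list(mask = full,
         contour = cbind(x = oc[, 2], y = oc[, 1]),
         area = sum(full),
         c_in = 255 * cin, c_out = 255 * cout),
    class = "region_boundary", energy = energies)
}

# number of 4-neighbors labeled TRUE (borders count as FALSE)
shift_sum <- function(L) {
  n <- nrow(L); m <- ncol(L)
  s <- matrix(0, n, m)
  s[-1, ] <- s[-1, ] + L[-n, ]
  s[-n, ] <- s[-n, ] + L[-1, ]
  s[, -1] <- s[, -1] + L[, -m]
  s[, -m] <- s[, -m] + L[, -1]
  s
}

# Discrete segmentation energy (intensities already on [0,1]).
chan_vese_energy <- function(u, inside, M, mu, lambda_in, lambda_out,
                             cin = mean(u[inside]), cout = mean(u[M & !inside])) {
  len <- boundary_length(inside)
  mu * len +
    lambda_in * sum((u[inside] - cin)^2) +
    lambda_out * sum((u[M & !inside] - cout)^2)
}

# count of 4-adjacent pairs with discordant labels (frame border = outside)
boundary_length <- function(L) {
  n <- nrow(L); m <- ncol(L)
  sum(L[-n, ] != L[-1, ]) + sum(L[, -m] != L[, -1]) +
    sum(L[1, ]) + sum(L[n, ]) + sum(L[, 1]) + sum(L[, m])
}

#' Detect the pupil and the glint in one eye frame
#'
#' Runs the full per-frame chain: dark-region binarization and cleaning, rough
#' pupil circle by circular Hough transform, eye ROI around it, bright-spot
#' thresholding and Hough estimate of the glint inside the ROI, Chan-Vese
#' refinement of both regions under their adaptive masks, and geometric
#' centers. Pixels belonging to the glint are excluded from the pupil interior
#' before the pupil size (`pupil_area`) is counted.
#'
#' @param frame numeric matrix in `[0, 255]`.
#' @param config segmentation configuration, see [default_config()]
#'   (`$segmentation` element); `NULL` for defaults.
#' @return a `detection`: list with `pupil`, `glint` (region boundaries or
#'   `NULL`), `pupil_center`, `glint_center` (0-based `c(x, y)` or `NULL`),
#'   `pupil_area`, and `valid` (`TRUE` only when both pupil and glint were
#'   found, as gaze mapping needs both).
#' @export
detect_pupil_and_glint <- function(frame, config = NULL) {
  cfg <- merge_config(default_config()$segmentation, config)
  invalid <- structure(list(pupil = NULL, glint = NULL, pupil_center = NULL,
                            glint_center = NULL, pupil_area = NA_real_,
                            valid = FALSE), class = "detection")

  dark <- tryCatch(binarize_dark_regions(frame, cfg$binarize$threshold),
                   error = function(e) NULL)
  if (is.null(dark) || !any(dark)) return(invalid)
  cleaned <- clean_binary(dark, cfg$clean$open_radius, cfg$clean$median_size)
  if (!any(cleaned)) return(invalid)
  pupil_cht <- tryCatch(
    detect_circle_cht(cleaned, cfg$cht$radius_range, cfg$cht$min_votes),
    error = function(e) NULL)
  if (is.null(pupil_cht)) return(invalid)

  pupil <- tryCatch(
    refine_boundary_chan_vese(frame, pupil_cht,
                              mask_margin = cfg$mask$pupil_scale,
                              mu = cfg$chanvese$mu,
                              lambda_in = cfg$chanvese$lambda_in,
                              lambda_out = cfg$chanvese$lambda_out,
                              max_iter = cfg$chanvese$max_iter,
                              fill_holes = TRUE),
    error = function(e) NULL)
  if (is.null(pupil)) return(invalid)
  pupil_center <- mask_centroid(pupil$mask)

  # glint path inside the eye ROI
  half <- cfg$roi$scale * pupil_cht$radius
  r0 <- max(1L, floor(pupil_cht$center[[2]] - half) + 1L)
  r1 <- min(nrow(frame), ceiling(pupil_cht$center[[2]] + half) + 1L)
  c0 <- max(1L, floor(pupil_cht$center[[1]] - half) + 1L)
  c1 <- min(ncol(frame), ceiling(pupil_cht$center[[1]] + half) + 1L)
  roi <- frame[r0:r1, c0:c1, drop = FALSE]
  thr <- max(cfg$glint$threshold_frac * max(roi), cfg$glint$min_intensity)
  bright <- matrix(FALSE, nrow(frame), ncol(frame))
  bright[r0:r1, c0:c1] <- roi >= thr
  bright <- clean_binary(bright, open_radius = cfg$glint$open_radius, median_size = 3)

  glint <- NULL; glint_center <- NULL
  if (any(bright)) {
    glint_cht <- tryCatch(
      detect_circle_cht(bright, cfg$cht$glint_radius_range, cfg$cht$glint_min_votes),
      error = function(e) NULL)
    if (!is.null(glint_cht)) {
      glint <- tryCatch(
        refine_boundary_chan_vese(frame, glint_cht,
                                  mask_margin = cfg$mask$glint_scale,
                                  mu = cfg$chanvese$mu,
                                  lambda_in = cfg$chanvese$lambda_in,
                                  lambda_out = cfg$chanvese$lambda_out,
                                  max_iter = cfg$chanvese$max_iter,
                                  mask_min_radius = cfg$mask$glint_min_radius),
        error = function(e) NULL)
      if (!is.null(glint)) glint_center <- mask_centroid(glint$mask)
    }
  }

  pupil_area <- if (is.null(glint)) pupil$area else sum(pupil$mask & !glint$mask)
  structure(list(pupil = pupil, glint = glint,
                 pupil_center = pupil_center, glint_center = glint_center,
                 pupil_area = pupil_area,
                 valid = !is.null(glint)),
            class = "detection")
}

#' Run detection over a sequence of frames
#'
#' @param frames a list of frame matrices, or a manifest tibble with columns
#'   `frame_index` and `path` (8-bit grayscale PNG files).
#' @param eye eye side label recorded in the output.
#' @param config see [detect_pupil_and_glint()].
#' @return tibble with one row per frame: `frame_index`, `eye`, `pupil_x`,
#'   `pupil_y`, `pupil_area`, `glint_x`, `glint_y`, `valid`.
#' @export
detect_session <- function(frames, eye = "right", config = NULL) {
  if (is.data.frame(frames)) {
    idx <- frames$frame_index
    get_frame <- function(i) read_eye_frame(frames$path[[i]])
    n <- nrow(frames)
  } else {
    idx <- seq_along(frames) - 1L
    get_frame <- function(i) frames[[i]]
    n <- length(frames)
  }
  rows <- purrr::map(seq_len(n), function(i) {
    det <- detect_pupil_and_glint(get_frame(i), config)
    tibble(
      frame_index = idx[i], eye = eye,
      pupil_x = if (is.null(det$pupil_center)) NA_real_ else det$pupil_center[[1]],
      pupil_y = if (is.null(det$pupil_center)) NA_real_ else det$pupil_center[[2]],
      pupil_area = det$pupil_area,
      glint_x = if (is.null(det$glint_center)) NA_real_ else det$glint_center[[1]],
      glint_y = if (is.null(det$glint_center)) NA_real_ else det$glint_center[[2]],
      valid = det$valid)
  })
  bind_rows(rows)
}

#' Read an 8-bit grayscale PNG as an intensity matrix
#'
#' @param path file path.
#' @return numeric matrix in `[0, 255]`.
#' @export
read_eye_frame <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  round(a * 255)
}

#' Write an intensity matrix as an 8-bit grayscale PNG
#'
#' @param frame numeric matrix in `[0, 255]`.
#' @param path file path.
#' @export
write_eye_frame <- function(frame, path) {
  png::writePNG(clamp(frame, 0, 255) / 255, path)
  invisible(path)
}
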