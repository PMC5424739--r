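# Pupil/glint segmentation: binarization, cleaning, Hough estimate,
# Chan-Vese refinement, and the full per-frame detector.

test_that("dark-region binarization handles fixed and automatic thresholds", {
  expect_equal(binarize_dark_regions(matrix(128, 70, 70), 50),
               matrix(FALSE, 70, 70))

  f <- two_level_frame()
  truth <- f == 20
  expect_identical(binarize_dark_regions(f, 60), truth)

  # "auto" picks an Otsu-style split; oracle: exhaustive inter-class-variance
  # sweep over all integer thresholds of the two-level histogram
  auto <- binarize_dark_regions(f, "auto")
  sweep_var <- vapply(1:254, function(t) {
    lo <- f[f < t]; hi <- f[f >= t]
    if (!length(lo) || !length(hi)) return(-Inf)
    length(lo) * length(hi) * (mean(lo) - mean(hi))^2
  }, numeric(1))
  t_star <- which.max(sweep_var)
  expect_true(t_star > 20 && t_star <= 150)
  expect_lt(abs(sum(auto) - sum(truth)) / sum(truth), 0.10)

  expect_error(binarize_dark_regions(matrix(77, 64, 64), "auto"),
               "degenerate histogram")
})

test_that("binary cleaning removes speckles and fills notches", {
  m <- matrix(FALSE, 100, 100)
  m[gazefuzz:::disk_mask(100, 100, 50, 50, 18)] <- TRUE
  set.seed(11)
  specks <- cbind(sample(1:100, 50, TRUE), sample(1:100, 50, TRUE))
  specks <- specks[gazefuzz:::disk_mask(100, 100, 50, 50, 25)[specks] == FALSE, , drop = FALSE]
  noisy <- m
  noisy[specks] <- TRUE
  cleaned <- clean_binary(noisy, open_radius = 2, median_size = 3)
  expect_equal(sum(cleaned & !m), 0)
  expect_gt(sum(cleaned & m) / sum(m), 0.95)

  expect_equal(clean_binary(matrix(FALSE, 10, 10)), matrix(FALSE, 10, 10))

  # one-pixel notches just inside the boundary are filled by the majority
  # filter; oracle is a direct neighborhood-majority computation
  disk <- gazefuzz:::disk_mask(60, 60, 30, 30, 15)
  notched <- disk
  notch_at <- which(gazefuzz:::disk_mask(60, 60, 30, 30, 12) &
                    !gazefuzz:::disk_mask(60, 60, 30, 30, 11))[c(3, 17, 31)]
  notched[notch_at] <- FALSE
  med <- clean_binary(notched, open_radius = 0, median_size = 3)
  majority <- matrix(FALSE, 60, 60)
  for (i in 1:60) for (j in 1:60) {
    cnt <- 0L
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= 60 && jj >= 1 && jj <= 60 && notched[ii, jj]) cnt <- cnt + 1L
    }
    majority[i, j] <- cnt > 4L
  }
  expect_identical(med, majority)
  expect_true(all(med[notch_at]))
})

test_that("circular Hough transform finds the strongest circle", {
  ring <- function(nr, nc, cx, cy, r) {
    gazefuzz:::disk_mask(nr, nc, cx, cy, r + 0.5) &
      !gazefuzz:::disk_mask(nr, nc, cx, cy, r - 0.5)
  }
  m <- ring(80, 80, 40, 40, 15)
  est <- detect_circle_cht(m, c(10, 20))
  expect_lte(max(abs(est$center - c(40, 40))), 1)
  expect_lte(abs(est$radius - 15), 1)

  # two circles: the larger one has more edge pixels, hence more votes;
  # oracle: brute-force accumulator over all centers and radii
  m2 <- ring(80, 110, 30, 40, 15) | ring(80, 110, 85, 40, 5)
  est2 <- detect_circle_cht(m2, c(3, 20))
  brute_best <- list(score = -1)
  ep <- which(m2, arr.ind = TRUE)
  for (r in 3:20) for (cx in seq(20, 95, by = 1)) for (cy in seq(30, 50, by = 1)) {
    d <- sqrt((ep[, 2] - 1 - cx)^2 + (ep[, 1] - 1 - cy)^2)
    v <- sum(d >= r - 0.5 & d < r + 0.5)
    if (v > brute_best$score) brute_best <- list(score = v, cx = cx, cy = cy, r = r)
  }
  expect_equal(est2$radius, brute_best$r)
  expect_equal(unname(est2$center), c(brute_best$cx, brute_best$cy))
  expect_equal(est2$score, brute_best$score)

  expect_error(detect_circle_cht(matrix(FALSE, 40, 40), c(5, 10)), "no circle")
})

test_that("Chan-Vese refinement recovers two-level regions and their means", {
  f <- two_level_frame(cx = 60, cy = 50, r = 20)
  seed <- structure(list(center = c(x = 62, y = 48), radius = 18, score = 1),
                    class = "circle_estimate")
  rb <- refine_boundary_chan_vese(f, seed)
  true_area <- sum(f == 20)
  expect_lt(abs(rb$area - true_area) / true_area, 0.02)
  expect_lt(abs(rb$c_in - 20), 2)
  expect_lt(abs(rb$c_out - 150), 2)
  expect_equal(rb$area, sum(rb$mask))

  # with noise, the recovered centroid stays within 1 px of the noiseless one
  set.seed(5)
  fn <- gazefuzz:::clamp(f + rnorm(length(f), 0, 10), 0, 255)
  rbn <- refine_boundary_chan_vese(fn, seed)
  truth_centroid <- gazefuzz:::mask_centroid(f == 20)
  expect_lt(max(abs(gazefuzz:::mask_centroid(rbn$mask) - truth_centroid)), 1)
})

test_that("Chan-Vese follows a non-circular chord-cut pupil", {
  f <- matrix(150, 100, 120)
  xs <- matrix(0:119, 100, 120, byrow = TRUE)
  ys <- matrix(0:99, 100, 120)
  truth <- (xs - 60)^2 + (ys - 50)^2 <= 20^2 & xs <= 68   # disk with flat chord
  f[truth] <- 20
  seed <- structure(list(center = c(x = 58, y = 50), radius = 19, score = 1),
                    class = "circle_estimate")
  rb <- refine_boundary_chan_vese(f, seed, mask_margin = 1.6)
  expect_lt(abs(rb$area - sum(truth)) / sum(truth), 0.03)
  # the boundary respects the chord: almost nothing beyond the cut line
  expect_lt(sum(rb$mask & xs > 69), 0.01 * sum(truth))
})

test_that("Chan-Vese energy is non-increasing and the result is idempotent", {
  set.seed(9)
  f <- two_level_frame()
  f <- gazefuzz:::clamp(f + rnorm(length(f), 0, 8), 0, 255)
  seed <- structure(list(center = c(x = 57, y = 52), radius = 17, score = 1),
                    class = "circle_estimate")
  rb <- refine_boundary_chan_vese(f, seed)
  e <- attr(rb, "energy")
  expect_gte(length(e), 1)
  expect_true(all(diff(e) <= 1e-9))

  reseed <- structure(list(center = unname(gazefuzz:::mask_centroid(rb$mask)),
                           radius = sqrt(rb$area / pi), score = 1),
                      class = "circle_estimate")
  rb2 <- refine_boundary_chan_vese(f, reseed)
  expect_lt(abs(rb2$area - rb$area) / rb$area, 0.01)
})

test_that("full detector finds pupil and glint centers and handles failures", {
  fr <- gen_eye_frame(pupil_center = c(80, 60), pupil_radius = 22,
                      glint_center = c(85, 55), glint_radius = 4, noise_sigma = 0)
  det <- detect_pupil_and_glint(fr)
  expect_true(det$valid)
  expect_lt(max(abs(det$pupil_center - c(80, 60))), 2)
  expect_lt(max(abs(det$glint_center - c(85, 55))), 1)
  # glint pixels are excluded from the pupil pixel count
  expect_lt(det$pupil_area, det$pupil$area)
  # centroid consistency
  expect_equal(unname(det$pupil_center), unname(gazefuzz:::mask_centroid(det$pupil$mask)))
  expect_equal(unname(det$glint_center), unname(gazefuzz:::mask_centroid(det$glint$mask)))

  expect_false(detect_pupil_and_glint(matrix(140, 120, 160))$valid)

  no_glint <- gen_eye_frame(glint_center = NULL)
  det2 <- detect_pupil_and_glint(no_glint)
  expect_false(det2$valid)
  expect_null(det2$glint)
  expect_lt(max(abs(det2$pupil_center - c(80, 60))), 2)
})

test_that("detected centers are equivariant under frame translation", {
  base <- list(p = c(70, 55), g = c(75, 50))
  d0 <- detect_pupil_and_glint(gen_eye_frame(pupil_center = base$p,
                                             glint_center = base$g,
                                             noise_sigma = 0))
  for (shift in list(c(6, 3), c(-5, 8))) {
    d1 <- detect_pupil_and_glint(gen_eye_frame(pupil_center = base$p + shift,
                                               glint_center = base$g + shift,
                                               noise_sigma = 0))
    expect_lt(max(abs(d1$pupil_center - d0$pupil_center - shift)), 0.5)
    expect_lt(max(abs(d1$glint_center - d0$glint_center - shift)), 0.5)
  }
})

test_that("detection tables round-trip through PNG frames", {
  dir <- withr::local_tempdir()
  fr <- gen_eye_frame(noise_sigma = 3, seed = 2)
  write_eye_frame(fr, file.path(dir, "0.png"))
  back <- read_eye_frame(file.path(dir, "0.png"))
  expect_equal(dim(back), dim(fr))
  expect_lt(max(abs(back - fr)), 0.51)

  tab <- detect_session(list(fr))
  expect_named(tab, c("frame_index", "eye", "pupil_x", "pupil_y", "pupil_area",
                      "glint_x", "glint_y", "valid"))
  expect_true(tab$valid[1])
})
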