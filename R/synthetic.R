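# Ground-truthed synthetic inputs for every pipeline stage: NIR-style eye
# frames (dark pupil, bright corneal glint, mid-gray iris, Gaussian sensor
# noise), pupil-size series with constriction events, gaze traces with
# fixation and saccade segments, and monitor images of controllable texture
# density. Everything is integer-seeded and fully reproducible.

#' Render one synthetic NIR eye frame
#'
#' Iris-level background, dark pupil disc (optionally cut by a chord so the
#' pupil is deliberately non-elliptical), bright glint disc drawn on top, plus
#' additive Gaussian sensor noise clipped to `[0, 255]`.
#'
#' @param width,height frame size, px.
#' @param pupil_center,glint_center 0-based `c(x, y)`; `glint_center = NULL`
#'   renders a glint-free frame.
#' @param pupil_radius,glint_radius px.
#' @param pupil_level,iris_level,glint_level intensities in `[0, 255]`.
#' @param noise_sigma Gaussian noise standard deviation (0 = noiseless).
#' @param chord optional `list(angle =, dist =)`: pupil pixels whose signed
#'   distance along `angle` (radians) from the pupil center exceeds `dist`
#'   are cut away, flattening one side of the pupil.
#' @param seed RNG seed for the noise (`NULL` = use current RNG state).
#' @return numeric intensity matrix with a `truth` attribute (the geometry).
#' @export
gen_eye_frame <- function(width = 160, height = 120,
                          pupil_center = c(80, 60), pupil_radius = 22,
                          glint_center = c(85, 55), glint_radius = 4,
                          pupil_level = 25, iris_level = 120, glint_level = 250,
                          noise_sigma = 0, chord = NULL, seed = NULL) {
  if (pupil_center[[1]] - pupil_radius < 0 ||
      pupil_center[[1]] + pupil_radius > width - 1 ||
      pupil_center[[2]] - pupil_radius < 0 ||
      pupil_center[[2]] + pupil_radius > height - 1) {
    abort("invalid scene: pupil out of frame")
  }
  frame <- matrix(iris_level, height, width)
  pmask <- disk_mask(height, width, pupil_center[[1]], pupil_center[[2]], pupil_radius)
  if (!is.null(chord)) {
    xs <- matrix(0:(width - 1), height, width, byrow = TRUE)
    ys <- matrix(0:(height - 1), height, width)
    proj <- (xs - pupil_center[[1]]) * cos(chord$angle) +
      (ys - pupil_center[[2]]) * sin(chord$angle)
    pmask <- pmask & proj <= chord$dist
  }
  frame[pmask] <- pupil_level
  gmask <- NULL
  if (!is.null(glint_center)) {
    gmask <- disk_mask(height, width, glint_center[[1]], glint_center[[2]], glint_radius)
    frame[gmask] <- glint_level
  }
  if (noise_sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    frame <- clamp(frame + rnorm(length(frame), 0, noise_sigma), 0, 255)
  }
  attr(frame, "truth") <- list(
    pupil_center = pupil_center, pupil_radius = pupil_radius,
    pupil_mask_area = sum(pmask),
    glint_center = glint_center, glint_radius = glint_radius,
    pupil_level = pupil_level, iris_level = iris_level,
    glint_level = glint_level, noise_sigma = noise_sigma)
  frame
}

#' Generate a monitor image of controllable texture density
#'
#' Divides the screen into cells and fills a `density` fraction of them with
#' band-limited texture patches (smoothed white noise re-scaled to a set
#' contrast) on a flat background. Patch centers are recorded in the
#' `patches` attribute.
#'
#' @param density fraction of cells textured, in `[0, 1]`.
#' @param width,height monitor size, px.
#' @param cell cell pitch, px.
#' @param patch_size patch side, px (`<= cell`).
#' @param background background level in `[0, 255]`.
#' @param contrast texture standard deviation in intensity units.
#' @param seed RNG seed.
#' @return numeric matrix with attribute `patches` (tibble `x`, `y`).
#' @export
gen_monitor_image <- function(density, width = 1680, height = 1050, cell = 168,
                              patch_size = 100, background = 128, contrast = 60,
                              seed = 1) {
  stopifnot(density >= 0, density <= 1)
  set.seed(seed)
  img <- matrix(background, height, width)
  cx <- seq(cell / 2, width - cell / 2, by = cell)
  cy <- seq(cell / 2, height - cell / 2, by = cell)
  cells <- expand.grid(x = cx, y = cy)
  n_on <- round(density * nrow(cells))
  if (n_on > 0) {
    on <- sort(sample.int(nrow(cells), n_on))
    for (i in on) {
      img <- paint_patch(img, cells$x[i], cells$y[i], patch_size, contrast)
    }
    attr(img, "patches") <- tibble(x = cells$x[on], y = cells$y[on])
  } else {
    attr(img, "patches") <- tibble(x = numeric(0), y = numeric(0))
  }
  img
}

# draw one smoothed-noise texture patch centered at (x, y), 0-based coords
paint_patch <- function(img, x, y, patch_size, contrast) {
  h <- patch_size %/% 2
  r0 <- max(1L, round(y) - h + 1L); r1 <- min(nrow(img), round(y) + h + 1L)
  c0 <- max(1L, round(x) - h + 1L); c1 <- min(ncol(img), round(x) + h + 1L)
  nr <- r1 - r0 + 1L; nc <- c1 - c0 + 1L
  noise <- matrix(rnorm(nr * nc), nr, nc)
  k <- matrix(1 / 9, 3, 3)
  sm <- conv2_reflect(noise, k)
  sm <- sm / stats::sd(sm) * contrast
  img[r0:r1, c0:c1] <- clamp(img[r0:r1, c0:c1] + sm, 0, 255)
  img
}

# The generating eye model: compensated pupil positions at the four monitor
# corners. A rectangle-to-rectangle correspondence keeps the bilinear map
# affine (c = g = 0) and therefore exactly invertible for trace generation.
session_eye_model <- function(width, height) {
  eye <- rbind(c(-20, -12), c(20, -12), c(-20, 12), c(20, 12))
  mon <- rbind(c(0, 0), c(width - 1, 0), c(0, height - 1), c(width - 1, height - 1))
  list(eye_points = eye, monitor_points = mon,
       model = fit_calibration(eye, mon))
}

invert_affine_model <- function(model, g) {
  k <- model$coeffs
  c((g[[1]] - k[["d"]]) / k[["a"]], (g[[2]] - k[["h"]]) / k[["f"]])
}

#' Generate a ground-truthed synthetic gaze session
#'
#' Alternates positive events (saccade onto a textured target, fixation with
#' sub-threshold gaze jitter, and a template-shaped pupil constriction
#' starting at the fixation onset) with negative events of two kinds: a
#' fixation without any pupil constriction on a blank screen region, and a
#' wandering gaze that sweeps across the textured area without settling.
#' Labels are balanced. The session carries the per-frame ground truth, an
#' idealized detection table (what a perfect segmenter would report), the
#' monitor image, the generating calibration, and the feature/fuzzy
#' configuration; frames can be rendered on demand with
#' [render_session_frame()] or all at once with `render = TRUE`.
#'
#' @param n_events number of events (half positive, half negative).
#' @param window feature window size, frames.
#' @param seed integer seed; the same seed reproduces the session exactly.
#' @param noise_sigma sensor-noise standard deviation used when frames are
#'   rendered.
#' @param event_frames frames per event (a 4-frame saccade lead-in followed by
#'   fixation or wandering).
#' @param frame_width,frame_height eye-frame size, px.
#' @param monitor_width,monitor_height monitor size, px.
#' @param dip_fraction peak fractional pupil-area constriction of positive
#'   events.
#' @param jitter_px fixational gaze jitter (standard deviation per coordinate,
#'   monitor px).
#' @param wander_step wandering-gaze step length, monitor px/frame.
#' @param area_noise physiological pupil-area noise (pixels, s.d.).
#' @param render render all eye frames into `$frames` (memory-heavy; default
#'   renders on demand).
#' @param config pipeline configuration overrides, see [default_config()].
#' @return a `gaze_session` list: `truth`, `detections`, `events`, `monitor`,
#'   `model`, `calibration`, `config`, `seed`, optionally `frames`.
#' @export
gen_session <- function(n_events = 40, window = 10, seed = 1, noise_sigma = 5,
                        event_frames = 16, frame_width = 160, frame_height = 120,
                        monitor_width = 1680, monitor_height = 1050,
                        dip_fraction = 0.2, jitter_px = 1.0, wander_step = 28,
                        area_noise = 6, render = FALSE, config = NULL) {
  stopifnot(n_events >= 1, event_frames >= window + 4)
  set.seed(seed)
  em <- session_eye_model(monitor_width, monitor_height)
  glint0 <- c(80, 58)
  base_radius <- 22
  base_area <- pi * base_radius^2

  # 3 x 3 target grid (textured); blank spots halfway between columns
  gx <- monitor_width * c(0.2, 0.5, 0.8)
  gy <- monitor_height * c(0.2, 0.5, 0.8)
  targets <- expand.grid(x = gx, y = gy)
  blanks <- expand.grid(x = monitor_width * c(0.35, 0.65), y = gy)
  monitor <- matrix(128, monitor_height, monitor_width)
  for (i in seq_len(nrow(targets))) {
    monitor <- paint_patch(monitor, targets$x[i], targets$y[i], 110, 60)
  }
  attr(monitor, "patches") <- tibble(x = targets$x, y = targets$y)

  lead_in <- 4L
  dip_template <- default_template_bank(window)[[2]]   # middle-dip profile
  labels <- rep(c("gazing", "non-gazing"), length.out = n_events)
  tn_kinds <- c("still_blank", "wander_texture")
  tn_i <- 0L

  truth_rows <- list(); event_rows <- list()
  prev_gaze <- c(monitor_width / 2, monitor_height / 2)
  frame0 <- 0L
  for (e in seq_len(n_events)) {
    lab <- labels[e]
    kind <- if (lab == "gazing") "tp" else {
      tn_i <- tn_i + 1L
      tn_kinds[(tn_i - 1L) %% 2L + 1L]
    }
    target <- switch(kind,
      tp = unlist(targets[sample.int(nrow(targets), 1), ]),
      still_blank = unlist(blanks[sample.int(nrow(blanks), 1), ]),
      wander_texture = unlist(targets[sample.int(nrow(targets), 1), ]))

    gaze <- matrix(NA_real_, event_frames, 2)
    if (kind == "wander_texture") {
      pos <- target + rnorm(2, 0, 60)
      ang <- runif(1, 0, 2 * pi)
      for (i in seq_len(event_frames)) {
        ang <- ang + rnorm(1, 0, 0.6)
        pos <- pos + wander_step * c(cos(ang), sin(ang))
        pos <- clamp(pos, c(60, 60), c(monitor_width - 61, monitor_height - 61))
        gaze[i, ] <- pos
      }
      fixation_start <- NA_integer_
    } else {
      # saccade lead-in from the previous gaze position onto the target
      for (i in seq_len(lead_in - 1)) {
        frac <- i / lead_in
        gaze[i, ] <- prev_gaze + frac * (target - prev_gaze) + rnorm(2, 0, 3)
      }
      for (i in lead_in:event_frames) {
        gaze[i, ] <- target + rnorm(2, 0, jitter_px)
      }
      fixation_start <- lead_in + 1L
    }
    prev_gaze <- gaze[event_frames, ]

    area <- base_area + rnorm(event_frames, 0, area_noise)
    if (kind == "tp") {
      idx <- fixation_start:(fixation_start + window - 1L)
      area[idx] <- area[idx] * (1 - dip_fraction * (1 - dip_template))
      if (fixation_start + window <= event_frames) {
        tail_idx <- (fixation_start + window):event_frames
        area[tail_idx] <- area[tail_idx] * (1 - dip_fraction * (1 - dip_template[window]))
      }
    }
    radius <- sqrt(area / pi)

    # slow common head drift moves pupil and glint together
    tt <- frame0 + seq_len(event_frames)
    drift_x <- 3 * sin(2 * pi * tt / 240)
    drift_y <- 2 * cos(2 * pi * tt / 300)
    pprime <- t(apply(gaze, 1, function(g) invert_affine_model(em$model, g)))
    truth_rows[[e]] <- tibble(
      frame_index = frame0 + seq_len(event_frames) - 1L,
      event_id = e, label = lab, kind = kind,
      fixation_start = if (is.na(fixation_start)) NA_integer_ else frame0 + fixation_start - 1L,
      gaze_x = gaze[, 1], gaze_y = gaze[, 2],
      pupil_x = glint0[1] + drift_x + pprime[, 1],
      pupil_y = glint0[2] + drift_y + pprime[, 2],
      pupil_radius = radius, pupil_area = area,
      glint_x = glint0[1] + drift_x, glint_y = glint0[2] + drift_y)
    event_rows[[e]] <- tibble(event_id = e, label = lab, kind = kind,
                              start_frame = frame0,
                              target_x = target[[1]], target_y = target[[2]])
    frame0 <- frame0 + event_frames
  }
  truth <- bind_rows(truth_rows)
  events <- bind_rows(event_rows)

  detections <- tibble(
    frame_index = truth$frame_index, eye = "right",
    pupil_x = truth$pupil_x, pupil_y = truth$pupil_y,
    pupil_area = truth$pupil_area,
    glint_x = truth$glint_x, glint_y = truth$glint_y, valid = TRUE)

  cfg <- merge_config(default_config(), config)
  cfg$features$window <- window
  session <- structure(list(
    truth = truth, detections = detections, events = events,
    monitor = monitor, model = em$model,
    calibration = list(eye_points = em$eye_points, monitor_points = em$monitor_points),
    config = cfg, seed = seed, noise_sigma = noise_sigma,
    frame_width = frame_width, frame_height = frame_height,
    event_frames = event_frames), class = "gaze_session")
  if (render) {
    session$frames <- lapply(seq_len(nrow(truth)), function(i) {
      render_session_frame(session, i)
    })
  }
  session
}

#' Render the i-th eye frame of a synthetic session
#'
#' @param session a `gaze_session`.
#' @param i 1-based row index into `session$truth`.
#' @return intensity matrix (deterministic: the noise seed is derived from the
#'   session seed and the frame index).
#' @export
render_session_frame <- function(session, i) {
  tr <- session$truth[i, ]
  gen_eye_frame(width = session$frame_width, height = session$frame_height,
                pupil_center = c(tr$pupil_x, tr$pupil_y),
                pupil_radius = tr$pupil_radius,
                glint_center = c(tr$glint_x, tr$glint_y),
                noise_sigma = session$noise_sigma,
                seed = (session$seed * 131071 + i) %% 2147483647)
}

#' @export
print.gaze_session <- function(x, ...) {
  cat(sprintf("Synthetic gaze session: %d events (%d gazing / %d non-gazing), %d frames, seed %d\n",
              nrow(x$events), sum(x$events$label == "gazing"),
              sum(x$events$label != "gazing"), nrow(x$truth), x$seed))
  invisible(x)
}

#' Write a session to disk / read it back
#'
#' Writes `frames/<index>.png`, `monitor.png`, `truth.csv`, `events.csv`,
#' `detections.csv`, `calibration.json` and `config.yaml` under `dir`.
#'
#' @param session a `gaze_session`.
#' @param dir output directory.
#' @param write_frames render and write the eye frames (slow for long
#'   sessions).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir, write_frames = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(session$truth, file.path(dir, "truth.csv"))
  readr::write_csv(session$events, file.path(dir, "events.csv"))
  readr::write_csv(session$detections, file.path(dir, "detections.csv"))
  write_eye_frame(session$monitor, file.path(dir, "monitor.png"))
  cal <- session$calibration
  jsonlite::write_json(
    list(points = lapply(1:4, function(k) list(
      eye_side = "right",
      pupil_xy = cal$eye_points[k, ] + c(80, 58),
      glint_xy = c(80, 58),
      monitor_xy = cal$monitor_points[k, ]))),
    file.path(dir, "calibration.json"), auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(session$config, file.path(dir, "config.yaml"))
  if (write_frames) {
    fdir <- file.path(dir, "frames")
    dir.create(fdir, showWarnings = FALSE)
    for (i in seq_len(nrow(session$truth))) {
      write_eye_frame(render_session_frame(session, i),
                      file.path(fdir, sprintf("%05d.png", session$truth$frame_index[i])))
    }
  }
  invisible(dir)
}
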