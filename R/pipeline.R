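# End-to-end pipeline: configuration, per-event feature extraction, fuzzy
# scoring, and artifact writing.

#' Default pipeline configuration
#'
#' Nested list with every tunable parameter. Unknown keys in overrides are
#' rejected by [merge_config()].
#'
#' @return nested list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    segmentation = list(
      binarize = list(threshold = "auto"),
      clean = list(open_radius = 2, median_size = 3),
      cht = list(radius_range = c(12, 30), min_votes = 6,
                 glint_radius_range = c(2, 8), glint_min_votes = 6),
      glint = list(threshold_frac = 0.9, min_intensity = 180, open_radius = 1),
      chanvese = list(mu = 0.05, lambda_in = 1, lambda_out = 1, max_iter = 200),
      mask = list(pupil_scale = 1.5, glint_scale = 2.0, glint_min_radius = 8),
      roi = list(scale = 3)),
    features = list(
      window = 10, still_threshold = 5, min_amplitude_frac = 0.05,
      roi_half_width = 50, roi_half_height = 50),
    fuzzy = list(
      mode = "MIN", method = "COG", threshold = 0.5,
      membership = "gap"),
    session = list(fps = 30))
}

#' Merge a configuration override into defaults
#'
#' Recursive merge; any key in `override` that does not exist in `defaults`
#' is an error, so typos in config files fail loudly.
#'
#' @param defaults,override nested lists.
#' @param path key prefix used in error messages (internal).
#' @return merged nested list.
#' @export
merge_config <- function(defaults, override, path = "") {
  if (is.null(override)) return(defaults)
  for (k in names(override)) {
    if (!k %in% names(defaults)) {
      abort(sprintf("unknown config key: %s%s", path, k))
    }
    if (is.list(defaults[[k]]) && is.list(override[[k]])) {
      defaults[[k]] <- merge_config(defaults[[k]], override[[k]],
                                    paste0(path, k, "."))
    } else {
      defaults[[k]] <- override[[k]]
    }
  }
  defaults
}

#' Per-event feature extraction
#'
#' For each event: builds the glint-compensated gaze trace, locates the
#' fixation onset (longest still run of per-frame gaze change below the
#' stillness threshold; if no run is long enough the lowest-total-change
#' candidate window is used and flagged), and computes the three raw
#' features over the anchored window: template-matching score of the
#' smoothed, min-max-normalized pupil-size window (Feature 1), cumulative
#' gaze change (Feature 2), and mean Gabor magnitude of the monitor ROI at
#' the window's mean gaze position (Feature 3).
#'
#' @param session a `gaze_session` (see [gen_session()]); its `detections`
#'   table may carry `gaze_x_noise` / `gaze_y_noise` columns (added by
#'   [noise_experiment()]) which are applied to the mapped gaze positions.
#' @param detections optional replacement detection table (e.g. the output of
#'   [detect_session()] on rendered frames).
#' @param bank template bank for Feature 1.
#' @return tibble: one row per event with `event_id`, `gazing`,
#'   `fixation_found`, `window_start` (global frame index), `best_template`,
#'   `f1_raw`, `f2_raw`, `f3_raw`.
#' @export
extract_features <- function(session, detections = NULL, bank = NULL) {
  cfg <- session$config
  W <- cfg$features$window
  if (is.null(bank)) bank <- default_template_bank(W)
  det <- detections %||% session$detections
  gabor <- build_bank()

  rows <- purrr::map(seq_len(nrow(session$events)), function(e) {
    ev <- session$events[e, ]
    idx <- which(session$truth$event_id == ev$event_id)
    d <- det[det$frame_index %in% session$truth$frame_index[idx], , drop = FALSE]
    tr <- gaze_trace(d, session$model)
    if ("gaze_x_noise" %in% names(d)) {
      tr$gx <- tr$gx + d$gaze_x_noise
      tr$gy <- tr$gy + d$gaze_y_noise
      tr$dz <- c(NA_real_, sqrt(diff(tr$gx)^2 + diff(tr$gy)^2))
    }
    dz <- tr$dz
    dz_f <- ifelse(is.na(dz), Inf, dz)
    n <- length(dz)
    out <- tibble(event_id = ev$event_id, gazing = ev$label == "gazing",
                  fixation_found = NA, window_start = NA_integer_,
                  best_template = NA_integer_,
                  f1_raw = NA_real_, f2_raw = NA_real_, f3_raw = NA_real_)
    if (n < W + 1) return(out)
    S <- tryCatch(locate_window_start(dz_f, W, cfg$features$still_threshold),
                  error = function(e) NA_integer_)
    found <- !is.na(S)
    if (!found) {
      # fallback: the candidate window with the least total gaze change
      cands <- 2:(n - W + 1)
      sums <- vapply(cands, function(s) sum(dz_f[s:(s + W - 1)]), numeric(1))
      if (all(!is.finite(sums))) return(out)
      S <- cands[which.min(sums)]
    }
    S <- min(S, n - W + 1)
    if (S < 1) return(out)
    sizes <- d$pupil_area
    if (anyNA(sizes[S:(S + W - 1)])) return(out)
    f1 <- pupil_accommodation(sizes, S, bank, W,
                              min_amp_frac = cfg$features$min_amplitude_frac)
    f2 <- tryCatch(dwell_change(dz_f, S, W), error = function(e) NA_real_)
    gx <- mean(tr$gx[S:(S + W - 1)], na.rm = TRUE)
    gy <- mean(tr$gy[S:(S + W - 1)], na.rm = TRUE)
    f3 <- tryCatch(
      texture_score(session$monitor, c(gx, gy), gabor,
                    cfg$features$roi_half_width, cfg$features$roi_half_height),
      error = function(e) NA_real_)
    out$fixation_found <- found
    out$window_start <- d$frame_index[S]
    out$best_template <- f1$best_template
    out$f1_raw <- f1$score; out$f2_raw <- f2; out$f3_raw <- f3
    out
  })
  bind_rows(rows)
}

# Build the session's fuzzy system: feature ranges from the extracted
# features; membership parameters either the worked-example set or fitted to
# the labelled features by the maximum-entropy criterion.
pipeline_fuzzy_system <- function(features, config) {
  ok <- stats::complete.cases(features[, c("f1_raw", "f2_raw", "f3_raw")])
  f <- features[ok, ]
  ranges <- list(f1 = range(f$f1_raw), f2 = range(f$f2_raw), f3 = range(f$f3_raw))
  kind <- config$fuzzy$membership
  if (is.list(kind)) {
    params <- kind
  } else if (kind %in% c("gap", "cluster")) {
    fv <- normalize_features(f$f1_raw, f$f2_raw, f$f3_raw, ranges)
    params <- purrr::map(c(f1 = "f1", f2 = "f2", f3 = "f3"), function(ft) {
      if (kind == "gap") {
        fit_membership_gap(fv[f$gazing, ft], fv[!f$gazing, ft])
      } else {
        fit_membership_cluster(fv[, ft])
      }
    })
  } else if (kind == "entropy") {
    fv <- normalize_features(f$f1_raw, f$f2_raw, f$f3_raw, ranges)
    params <- list(
      f1 = fit_membership_entropy(fv[f$gazing, "f1"], fv[!f$gazing, "f1"]),
      f2 = fit_membership_entropy(fv[f$gazing, "f2"], fv[!f$gazing, "f2"]),
      f3 = fit_membership_entropy(fv[f$gazing, "f3"], fv[!f$gazing, "f3"]))
  } else {
    params <- example_membership_params()
  }
  fuzzy_system(params = params, mode = config$fuzzy$mode,
               method = config$fuzzy$method, threshold = config$fuzzy$threshold,
               feature_ranges = ranges)
}

#' Run the full target-selection pipeline on a session
#'
#' Detection (either the session's idealized detection table or, with
#' `use_frames = TRUE`, full image segmentation of the rendered frames),
#' per-event feature extraction, fuzzy scoring and thresholded decisions,
#' and (when labels are present) an EER evaluation.
#'
#' @param session a `gaze_session`.
#' @param config configuration overrides.
#' @param use_frames segment rendered eye frames instead of using the
#'   idealized detections.
#' @param out_dir if non-`NULL`, write `features.csv`, `decisions.csv`, a
#'   `config_echo.yaml` and `eer.json` there.
#' @param quiet suppress progress messages.
#' @return list with `detections`, `features`, `scores` (features + `score`,
#'   `decision`), `fuzzy` (the fitted system), `eer` (an `eer_result` or
#'   `NULL`).
#' @export
run_pipeline <- function(session, config = NULL, use_frames = FALSE,
                         out_dir = NULL, quiet = FALSE) {
  cfg <- merge_config(session$config, config)
  session$config <- cfg
  if (!quiet) {
    message(sprintf("window: %d frames at %g fps = %.0f ms",
                    cfg$features$window, cfg$session$fps,
                    window_duration_ms(cfg$features$window, cfg$session$fps)))
  }
  detections <- session$detections
  if (use_frames) {
    frames <- session$frames %||%
      lapply(seq_len(nrow(session$truth)), function(i) render_session_frame(session, i))
    detections <- detect_session(frames, config = cfg$segmentation)
    detections$frame_index <- session$truth$frame_index
  }
  features <- extract_features(session, detections = detections)
  fs <- pipeline_fuzzy_system(features, cfg)
  scores <- score_features(fs, features)
  scores$score[is.na(scores$score)] <- 0
  scores$decision[is.na(scores$decision)] <- "not_selected"
  eer <- NULL
  if (!is.null(scores$gazing) && length(unique(scores$gazing)) == 2) {
    eer <- compute_eer(tibble(score = scores$score, gazing = scores$gazing))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(features, file.path(out_dir, "features.csv"))
    readr::write_csv(scores, file.path(out_dir, "decisions.csv"))
    yaml::write_yaml(cfg, file.path(out_dir, "config_echo.yaml"))
    if (!is.null(eer)) {
      jsonlite::write_json(as.list(tidy(eer)), file.path(out_dir, "eer.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  list(detections = detections, features = features, scores = scores,
       fuzzy = fs, eer = eer)
}
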