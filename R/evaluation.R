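# Decision-quality evaluation against labels. A type I error misclassifies an
# intentional selection gaze (gazing / TP-class) as non-gazing; a type II
# error misclassifies a non-gazing episode as a selection. The equal error
# rate (EER) is the mean of the two at the threshold where they are closest.

check_scores <- function(scores) {
  stopifnot(is.data.frame(scores), all(c("score", "gazing") %in% names(scores)))
  g <- as.logical(scores$gazing)
  if (all(g) || !any(g)) abort("degenerate evaluation set: both classes required")
  g
}

#' Type I and type II error rates at a threshold
#'
#' With the strict decision rule (`selected` iff `score > threshold`):
#' type I = percentage of gazing items with `score <= threshold`,
#' type II = percentage of non-gazing items with `score > threshold`.
#'
#' @param scores tibble with columns `score` and `gazing` (logical:
#'   gazing-for-selection class).
#' @param threshold decision threshold.
#' @return tibble with `threshold`, `type1_pct`, `type2_pct`.
#' @export
error_rates <- function(scores, threshold) {
  g <- check_scores(scores)
  tibble(threshold = threshold,
         type1_pct = 100 * mean(scores$score[g] <= threshold),
         type2_pct = 100 * mean(scores$score[!g] > threshold))
}

#' Equal error rate by threshold sweep
#'
#' Sweeps every distinct score value as a threshold, picks the one minimizing
#' `|type I - type II|` (ties to the lower threshold), and reports the mean of
#' the two errors at that threshold.
#'
#' @param scores tibble with `score` and `gazing` columns.
#' @return an `eer_result`: tibble row with `threshold`, `type1_pct`,
#'   `type2_pct`, `eer_pct`.
#' @export
compute_eer <- function(scores) {
  g <- check_scores(scores)
  thr <- sort(unique(scores$score))
  sweep <- bind_rows(lapply(thr, function(t) error_rates(scores, t)))
  i <- which.min(abs(sweep$type1_pct - sweep$type2_pct))
  out <- sweep[i, ]
  out$eer_pct <- (out$type1_pct + out$type2_pct) / 2
  class(out) <- c("eer_result", class(out))
  out
}

#' @export
print.eer_result <- function(x, ...) {
  cat(sprintf("EER %.2f%% at threshold %.4g (type I %.2f%%, type II %.2f%%)\n",
              x$eer_pct, x$threshold, x$type1_pct, x$type2_pct))
  invisible(x)
}

#' @rdname compute_eer
#' @param x an `eer_result`.
#' @param ... unused.
#' @export
tidy.eer_result <- function(x, ...) {
  tibble(threshold = x$threshold, type1_pct = x$type1_pct,
         type2_pct = x$type2_pct, eer_pct = x$eer_pct)
}

#' @rdname compute_eer
#' @export
glance.eer_result <- function(x, ...) tidy(x)

#' ROC curve over the threshold sweep
#'
#' One point per distinct threshold (plus the everything-selected and
#' nothing-selected extremes), sorted by threshold. The axes follow the
#' biometric-verification convention `x = 100 - type II error (%)`,
#' `y = type I error (%)`; perfectly separable scores pass through
#' `(100, 0)`.
#'
#' @param scores tibble with `score` and `gazing` columns.
#' @return a `roc_curve` tibble with `threshold`, `type1_pct`, `type2_pct`,
#'   `x` (= `100 - type2_pct`) and `y` (= `type1_pct`).
#' @export
roc_curve <- function(scores) {
  check_scores(scores)
  thr <- sort(unique(scores$score))
  thr <- c(min(thr) - 1, thr)   # everything-selected extreme
  sweep <- bind_rows(lapply(thr, function(t) error_rates(scores, t)))
  sweep$x <- 100 - sweep$type2_pct
  sweep$y <- sweep$type1_pct
  class(sweep) <- c("roc_curve", class(sweep))
  sweep
}

#' Plot a ROC curve
#' @param object a [roc_curve()] tibble.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "100 - type II error (%)", y = "type I error (%)") +
    ggplot2::coord_equal(xlim = c(0, 100), ylim = c(0, 100)) +
    ggplot2::theme_minimal()
}

#' Gaussian-noise robustness experiment
#'
#' Perturbs the detected pupil sizes and gaze coordinates of a session with
#' zero-mean Gaussian noise of each standard deviation in `sigmas`, re-runs
#' feature extraction, fuzzy calibration and scoring, and reports the EER per
#' sigma (averaged over `n_rep` seeded replicates). By default the fuzzy
#' system is re-calibrated on each perturbed run, simulating a tracker
#' operated and calibrated under that noise level; pass a fixed `fs` to
#' evaluate a frozen calibration instead.
#'
#' @param session a synthetic session from [gen_session()] (or any list with
#'   `detections`, `truth`, `monitor`, `model`, `config`).
#' @param sigmas noise standard deviations (pixels, applied to the pupil size
#'   in area-pixels and to each gaze coordinate in monitor px).
#' @param seed base RNG seed; replicate `r` draws one set of standard-normal
#'   perturbations (seeded with `seed + r`) that is scaled by every sigma, so
#'   the sigma levels are compared on common random numbers.
#' @param n_rep replicates per sigma.
#' @param fs optional frozen fuzzy system; `NULL` (default) re-calibrates on
#'   each perturbed run.
#' @return tibble with `sigma`, `rep`, `eer_pct` plus a summary attribute.
#' @export
noise_experiment <- function(session, sigmas = c(0, 5, 10, 20), seed = 1,
                             n_rep = 10, fs = NULL) {
  rows <- list()
  n <- nrow(session$detections)
  for (r in seq_len(n_rep)) {
    set.seed((seed + r) %% .Machine$integer.max)
    eps_area <- rnorm(n); eps_gx <- rnorm(n); eps_gy <- rnorm(n)
    for (sg in sigmas) {
      noisy <- session
      # pupil size is a pixel count, so its noise is in area pixels; gaze
      # noise is per monitor coordinate
      noisy$detections$pupil_area <- pmax(1, noisy$detections$pupil_area + sg * eps_area)
      noisy$detections$gaze_x_noise <- sg * eps_gx
      noisy$detections$gaze_y_noise <- sg * eps_gy
      feats <- extract_features(noisy)
      fs_run <- fs %||% pipeline_fuzzy_system(feats, session$config)
      scored <- score_features(fs_run, feats)
      eer <- compute_eer(tibble(score = scored$score, gazing = scored$gazing))
      rows[[length(rows) + 1]] <- tibble(sigma = sg, rep = r, eer_pct = eer$eer_pct)
    }
  }
  out <- bind_rows(rows)
  summ <- out %>% group_by(.data$sigma) %>%
    summarise(mean_eer_pct = mean(.data$eer_pct), .groups = "drop")
  attr(out, "summary") <- summ
  out
}

#' Minimum on-screen separation of selectable targets
#'
#' Converts the gaze tracker's angular accuracy into the minimum distance
#' between two targets at a given viewing distance:
#' `z * tan(2 * accuracy)` (the factor 2 keeps the targets' acceptance cones
#' disjoint). At 70 cm and +/-1 degree accuracy this is 2.44 cm.
#'
#' @param z_cm viewing distance, cm.
#' @param accuracy_deg one-sided angular accuracy, degrees.
#' @return separation in cm.
#' @export
min_target_separation_cm <- function(z_cm = 70, accuracy_deg = 1) {
  z_cm * tan(2 * accuracy_deg * pi / 180)
}

#' Frame period and window duration
#'
#' @param fps camera frame rate, frames/second.
#' @return `frame_period_ms()`: milliseconds per frame (33.3 ms at 30 fps).
#' @export
frame_period_ms <- function(fps = 30) 1000 / fps

#' @rdname frame_period_ms
#' @param window window size, frames.
#' @return `window_duration_ms()`: window duration in ms (333 ms for 10
#'   frames at 30 fps).
#' @export
window_duration_ms <- function(window = 10, fps = 30) window * 1000 / fps
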