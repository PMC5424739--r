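# Feature 1: pupil accommodation. The pupil-size series (pixel counts from
# segmentation) is smoothed, a 10-frame window anchored at the fixation onset
# is min-max normalized, and its sum-of-squared-differences distance to a bank
# of constriction templates is minimized; a small score means the size trace
# looks like an intentional-selection constriction.

#' Smooth a pupil-size series with a 3-tap moving average
#'
#' Uniform weights `1/3`; at the two endpoints the window is truncated and
#' renormalized to its support, so the length is preserved.
#'
#' @param sizes numeric vector of pupil pixel counts.
#' @return numeric vector, same length.
#' @export
smooth_series <- function(sizes) {
  n <- length(sizes)
  stopifnot(n >= 1)
  if (n == 1L) return(sizes)
  out <- numeric(n)
  out[1] <- mean(sizes[1:2])
  out[n] <- mean(sizes[(n - 1):n])
  if (n > 2L) {
    out[2:(n - 1)] <- (sizes[1:(n - 2)] + sizes[2:(n - 1)] + sizes[3:n]) / 3
  }
  out
}

#' Min-max normalize a window to `[0, 1]`
#'
#' A constant window (max = min) maps to all zeros; the result then carries no
#' accommodation evidence but still scores against the templates.
#'
#' @param window numeric vector.
#' @return numeric vector in `[0, 1]`.
#' @export
normalize_minmax <- function(window) {
  rng <- range(window)
  if (rng[1] == rng[2]) return(rep(0, length(window)))
  (window - rng[1]) / (rng[2] - rng[1])
}

#' Default constriction template bank
#'
#' Three length-`size` normalized "constrict then partially recover" profiles:
#' a fast, a middle, and a slow dip (minimum at positions 3, 5 and 7 of a
#' 10-point window), each descending linearly from 1 to 0 and recovering
#' linearly to `recover`. Users can substitute calibrated templates via a CSV
#' (one row per template) with [read_template_bank()].
#'
#' @param size window length in frames.
#' @param recover height recovered by the end of the window.
#' @return list of numeric templates, each normalized to min 0 and max 1.
#' @export
default_template_bank <- function(size = 10, recover = 0.6) {
  dips <- round(c(3, 5, 7) / 10 * size)
  purrr::map(dips, function(d) {
    down <- seq(1, 0, length.out = d)
    up <- seq(0, recover, length.out = size - d + 1)[-1]
    c(down, up)
  })
}

#' Read a template bank from CSV (one template per row)
#' @param path CSV path, no header, one row per template.
#' @return list of numeric templates.
#' @export
read_template_bank <- function(path) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))
}

#' Template-matching score for one normalized window
#'
#' `score = min_i sum_j (p_j - q_ij)^2` over the template bank; the minimizing
#' template and the SSD are returned. A lower score is stronger evidence of
#' the pupil constriction that accompanies intentional target selection.
#'
#' @param window normalized numeric vector.
#' @param bank list of templates, each the same length as `window`.
#' @return list with `score`, `best_template` (1-based index into `bank`).
#' @export
template_match_score <- function(window, bank) {
  stopifnot(length(bank) >= 1)
  lens <- vapply(bank, length, integer(1))
  if (any(lens != length(window))) abort("window/template length mismatch")
  ssd <- vapply(bank, function(q) sum((window - q)^2), numeric(1))
  list(score = min(ssd), best_template = which.min(ssd))
}

#' Locate the fixation onset that anchors the feature windows
#'
#' Finds the longest run of frames whose per-frame gaze change `dz` stays
#' below `still_threshold` and returns the first frame of that run (ties go to
#' the earlier run). This frame anchors both the template-matching window
#' (Feature 1) and the short-dwell window (Feature 2).
#'
#' @param dz numeric vector of per-frame gaze changes (monitor px); `dz[i]` is
#'   the change between frame `i` and frame `i - 1`.
#' @param window minimum run length (the feature window size).
#' @param still_threshold stillness bound, monitor px/frame.
#' @return 1-based index of the window start within `dz`.
#' @export
locate_window_start <- function(dz, window = 10, still_threshold = 5) {
  still <- dz < still_threshold
  r <- rle(still)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= window)
  if (length(ok) == 0L) abort("no fixation candidate")
  best <- ok[which.max(r$lengths[ok])]
  starts[best]
}

#' Raw Feature 1 for a pupil-size series
#'
#' Smooths the series, takes the `window`-frame slice starting at `start`,
#' min-max normalizes it, and scores it against the template bank.
#'
#' @param sizes pupil pixel counts, one per frame.
#' @param start 1-based window start index.
#' @param bank template bank; default [default_template_bank()].
#' @param window window size in frames.
#' @param min_amp_frac amplitude gate: a window whose peak-to-peak amplitude
#'   is below this fraction of its mean size carries no accommodation
#'   evidence (intentional constrictions are an order of magnitude larger)
#'   and is treated like a constant window — normalized to all zeros — so
#'   that min-max scaling does not inflate sub-physiological noise into a
#'   template-shaped curve. Set to 0 to disable.
#' @return list with `score` (raw Feature 1), `best_template`,
#'   `window_start`, `evidence` (`FALSE` when the amplitude gate or the
#'   constant-window rule fired).
#' @export
pupil_accommodation <- function(sizes, start, bank = default_template_bank(window),
                                window = 10, min_amp_frac = 0.05) {
  stopifnot(start >= 1, start + window - 1 <= length(sizes))
  sm <- smooth_series(sizes)
  w <- sm[start:(start + window - 1)]
  amp <- diff(range(w))
  evidence <- amp > 0 && amp >= min_amp_frac * mean(w)
  wn <- if (evidence) normalize_minmax(w) else rep(0, window)
  m <- template_match_score(wn, bank)
  list(score = m$score, best_template = m$best_template,
       window_start = start, evidence = evidence)
}
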