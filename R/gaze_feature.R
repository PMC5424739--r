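# Feature 2: change in gaze position over a short dwell window. The pupil
# center is compensated by the glint center (head-movement compensation of the
# pupil-center/corneal-reflection technique), mapped to monitor coordinates by
# a 4-point bilinear calibration, and the Euclidean per-frame gaze changes are
# summed over the dwell window.

#' Glint-compensated pupil position
#'
#' Vector difference `pupil_center - glint_center`; a common offset applied to
#' both centers (head translation) leaves the result unchanged.
#'
#' @param pupil_center,glint_center numeric `c(x, y)`.
#' @return numeric `c(x, y)`.
#' @export
compensate <- function(pupil_center, glint_center) {
  out <- c(pupil_center[[1]] - glint_center[[1]],
           pupil_center[[2]] - glint_center[[2]])
  names(out) <- c("x", "y")
  out
}

#' Fit the 4-point bilinear calibration
#'
#' Solves the two 4x4 linear systems so that
#' `Gx = a*x + b*y + c*x*y + d` and `Gy = e*x + f*y + g*x*y + h`
#' reproduce the four eye-point / monitor-corner correspondences exactly.
#'
#' @param eye_points 4x2 matrix of glint-compensated pupil positions
#'   (one row per calibration corner).
#' @param monitor_points 4x2 matrix of the corresponding monitor targets (px).
#' @return a `calibration_model`: list with `coeffs = c(a,b,c,d,e,f,g,h)`.
#' @export
fit_calibration <- function(eye_points, monitor_points) {
  eye_points <- as.matrix(eye_points); monitor_points <- as.matrix(monitor_points)
  stopifnot(all(dim(eye_points) == c(4, 2)), all(dim(monitor_points) == c(4, 2)))
  x <- eye_points[, 1]; y <- eye_points[, 2]
  A <- cbind(x, y, x * y, 1)
  if (abs(det(A)) < 1e-12) abort("degenerate calibration: eye points are collinear")
  cx <- solve(A, monitor_points[, 1])
  cy <- solve(A, monitor_points[, 2])
  structure(list(coeffs = setNames(c(cx, cy), letters[1:8])),
            class = "calibration_model")
}

#' Apply a calibration model to a compensated pupil position
#'
#' @param model a `calibration_model`.
#' @param p numeric `c(x, y)` glint-compensated pupil position, or an n x 2
#'   matrix of positions.
#' @return monitor-coordinate gaze point(s), same shape as `p`.
#' @export
apply_calibration <- function(model, p) {
  k <- model$coeffs
  if (is.matrix(p)) {
    cbind(x = k[1] * p[, 1] + k[2] * p[, 2] + k[3] * p[, 1] * p[, 2] + k[4],
          y = k[5] * p[, 1] + k[6] * p[, 2] + k[7] * p[, 1] * p[, 2] + k[8])
  } else {
    c(x = unname(k[1] * p[[1]] + k[2] * p[[2]] + k[3] * p[[1]] * p[[2]] + k[4]),
      y = unname(k[5] * p[[1]] + k[6] * p[[2]] + k[7] * p[[1]] * p[[2]] + k[8]))
  }
}

#' Map per-eye detections to a single gaze point
#'
#' Applies each eye's calibration to its compensated pupil position and
#' averages the two monitor-space gaze points; with one valid eye, that eye's
#' point is returned alone.
#'
#' @param model_left,model_right `calibration_model`s (either may be `NULL`).
#' @param p_left,p_right compensated pupil positions `c(x, y)` or `NULL` when
#'   that eye's detection is invalid.
#' @return monitor gaze point `c(x, y)`.
#' @export
map_gaze <- function(model_left = NULL, model_right = NULL,
                     p_left = NULL, p_right = NULL) {
  pts <- list()
  if (!is.null(model_left) && !is.null(p_left)) {
    pts <- c(pts, list(apply_calibration(model_left, p_left)))
  }
  if (!is.null(model_right) && !is.null(p_right)) {
    pts <- c(pts, list(apply_calibration(model_right, p_right)))
  }
  if (length(pts) == 0L) abort("gaze unavailable for frame: no valid eye")
  Reduce(`+`, pts) / length(pts)
}

#' Euclidean gaze change between consecutive frames
#'
#' @param p_now,p_prev gaze points `c(x, y)`.
#' @return the Euclidean distance (a horizontal change of 3 px and a vertical
#'   change of 4 px give 5, not 4).
#' @export
gaze_delta <- function(p_now, p_prev) {
  sqrt((p_now[[1]] - p_prev[[1]])^2 + (p_now[[2]] - p_prev[[2]])^2)
}

#' Raw Feature 2: cumulative gaze change over a short dwell window
#'
#' Sum of the per-frame Euclidean gaze changes over the `W` frames starting at
#' `S`. Smaller values mean the gaze is being held for target selection.
#'
#' @param dz numeric vector of per-frame gaze changes.
#' @param S 1-based window start index into `dz`.
#' @param W window size in frames.
#' @return the sum, `>= 0`.
#' @export
dwell_change <- function(dz, S, W) {
  if (S < 1 || S + W - 1 > length(dz) || anyNA(dz[S:(S + W - 1)])) {
    abort("incomplete dwell window")
  }
  sum(dz[S:(S + W - 1)])
}

#' Build a gaze trace from a detection table
#'
#' Compensates each valid detection by its glint, maps it through the
#' calibration model, and appends per-frame gaze changes.
#'
#' @param detections tibble from [detect_session()] (or the synthetic
#'   generator) with `frame_index`, `pupil_x`, `pupil_y`, `glint_x`, `glint_y`,
#'   `valid`.
#' @param model a `calibration_model` for this eye.
#' @return tibble `frame_index`, `gx`, `gy`, `dz` (NA for the first frame and
#'   after invalid frames).
#' @export
gaze_trace <- function(detections, model) {
  d <- detections
  px <- d$pupil_x - d$glint_x
  py <- d$pupil_y - d$glint_y
  g <- apply_calibration(model, cbind(px, py))
  gx <- ifelse(d$valid, g[, 1], NA_real_)
  gy <- ifelse(d$valid, g[, 2], NA_real_)
  dz <- c(NA_real_, sqrt(diff(gx)^2 + diff(gy)^2))
  tibble(frame_index = d$frame_index, gx = gx, gy = gy, dz = dz)
}

#' Read a 4-corner calibration record
#'
#' @param path JSON or YAML file with four records, each holding `pupil_xy`,
#'   `glint_xy` and `monitor_xy`.
#' @return a `calibration_model`.
#' @export
read_calibration <- function(path) {
  rec <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else jsonlite::read_json(path)
  pts <- rec$points %||% rec
  eye <- t(vapply(pts, function(p) {
    compensate(unlist(p$pupil_xy), unlist(p$glint_xy))
  }, numeric(2)))
  mon <- t(vapply(pts, function(p) unlist(p$monitor_xy), numeric(2)))
  fit_calibration(eye, mon)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
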