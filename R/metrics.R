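#' Fingertip velocity by finite differences
#'
#' Velocities (mm/s) are estimated from positions: central differences on
#' interior frames, one-sided differences at both ends. Central differences
#' remain valid under the irregular sampling the sensor can produce; no
#' smoothing or resampling is applied.
#'
#' @param trial a [palp_trial()].
#' @param finger `"index"` or `"middle"`.
#' @return a matrix with one row per frame and columns `vx, vy, vz` (mm/s).
#' @export
estimate_velocity <- function(trial, finger = c("index", "middle")) {
  finger <- match.arg(finger)
  pos <- finger_positions(trial, finger)
  t <- trial$frames$t_s
  n <- nrow(pos)
  if (any(diff(t) <= 0)) {
    palp_error("zero or negative time gap between frames", "palp_malformed_input")
  }
  v <- matrix(NA_real_, n, 3L, dimnames = list(NULL, c("vx", "vy", "vz")))
  v[1L, ] <- (pos[2L, ] - pos[1L, ]) / (t[2L] - t[1L])
  v[n, ] <- (pos[n, ] - pos[n - 1L, ]) / (t[n] - t[n - 1L])
  if (n > 2L) {
    idx <- 2L:(n - 1L)
    dt <- t[idx + 1L] - t[idx - 1L]
    v[idx, ] <- (pos[idx + 1L, , drop = FALSE] - pos[idx - 1L, , drop = FALSE]) / dt
  }
  v
}

finger_positions <- function(trial, finger) {
  fr <- trial$frames
  if (finger == "index") {
    cbind(x = fr$ix, y = fr$iy, z = fr$iz)
  } else {
    cbind(x = fr$mx, y = fr$my, z = fr$mz)
  }
}

#' Trial duration in seconds
#'
#' Time from the first to the last recorded frame.
#'
#' @param trial a [palp_trial()].
#' @return duration in seconds.
#' @export
compute_duration <- function(trial) {
  t <- trial$frames$t_s
  t[length(t)] - t[1L]
}

#' Total path length (TPL) in millimeters
#'
#' Cumulative 3D Euclidean distance traversed by one fingertip over the
#' trial. Finger lifts are real traversed path, so the full 3D displacement
#' is summed (unlike the in-plane quantities used for accuracy).
#'
#' @inheritParams estimate_velocity
#' @return total path length, mm.
#' @export
compute_tpl <- function(trial, finger = c("index", "middle")) {
  finger <- match.arg(finger)
  pos <- finger_positions(trial, finger)
  steps <- diff(pos)
  sum(sqrt(rowSums(steps^2)))
}

#' Final-frame accuracy in millimeters
#'
#' Distance from the true target to the participant's reported location:
#' the lesser of the index- and middle-fingertip distances, measured in the
#' skin plane (x, y) at the trial's final frame. The target sits under opaque
#' skin, so depth is not an estimable quantity and z is ignored.
#'
#' @param trial a [palp_trial()].
#' @return accuracy in mm (non-negative).
#' @export
compute_accuracy <- function(trial) {
  fr <- trial$frames[nrow(trial$frames), ]
  tx <- trial$target[[1L]]; ty <- trial$target[[2L]]
  d_index <- sqrt((fr$ix - tx)^2 + (fr$iy - ty)^2)
  d_middle <- sqrt((fr$mx - tx)^2 + (fr$my - ty)^2)
  min(d_index, d_middle)
}

#' Accuracy band classification
#'
#' A fingertip covers roughly a 10 mm-radius disc, so estimates within 10 mm
#' are accurate; within 30 mm, marginally accurate; beyond 30 mm, errors.
#' Bands are closed on the inner side: accurate = \[0, 10\],
#' marginal = (10, 30\], error = (30, Inf).
#'
#' @param accuracy_mm non-negative accuracy values, mm (vectorized).
#' @return factor with levels `accurate`, `marginal`, `error`.
#' @export
#' @examples
#' classify_accuracy(c(0, 10, 23.2, 30, 30.0001))
classify_accuracy <- function(accuracy_mm) {
  if (any(!is.finite(accuracy_mm)) || any(accuracy_mm < 0)) {
    palp_error("accuracy_mm must be finite and non-negative", "palp_domain_error")
  }
  cut(accuracy_mm, breaks = c(-Inf, 10, 30, Inf),
      labels = c("accurate", "marginal", "error"), right = TRUE)
}

#' Signed projected velocity toward the target
#'
#' Projects the in-plane velocity onto the unit vector from the fingertip's
#' in-plane position toward the target. A positive value means the finger is
#' closing on the target at that rate (mm/s); equivalently the negative time
#' derivative of the in-plane distance to the target.
#'
#' @param position numeric of length >= 2; only `(x, y)` are used (mm).
#' @param velocity numeric of length >= 2; only `(vx, vy)` are used (mm/s).
#' @param target numeric `c(x, y)` (mm).
#' @return signed scalar speed toward the target, mm/s.
#' @export
project_velocity <- function(position, velocity, target) {
  dx <- target[[1L]] - position[[1L]]
  dy <- target[[2L]] - position[[2L]]
  d <- sqrt(dx^2 + dy^2)
  if (d == 0) {
    palp_error("fingertip exactly at target: direction undefined",
               "palp_undefined_direction")
  }
  (velocity[[1L]] * dx + velocity[[2L]] * dy) / d
}

# Per-frame movement mask and projected velocities for one finger.
# A movement frame has 3D speed >= eps_mm_s; frames exactly on the target
# (undefined direction) are treated as non-movement.
frame_kinematics <- function(trial, finger, eps_mm_s) {
  pos <- finger_positions(trial, finger)
  vel <- estimate_velocity(trial, finger)
  speed3d <- sqrt(rowSums(vel^2))
  dx <- trial$target[[1L]] - pos[, 1L]
  dy <- trial$target[[2L]] - pos[, 2L]
  dist_plane <- sqrt(dx^2 + dy^2)
  moving <- speed3d >= eps_mm_s & dist_plane > 0
  vp <- rep(NA_real_, nrow(pos))
  ok <- dist_plane > 0
  vp[ok] <- (vel[ok, 1L] * dx[ok] + vel[ok, 2L] * dy[ok]) / dist_plane[ok]
  list(moving = moving, vp = vp, dist_plane = dist_plane)
}

#' Ratio of correct movement (RCM)
#'
#' Percentage of movement frames in which the projected velocity toward the
#' target is positive, i.e. the participant is palpating toward rather than
#' away from the vibration source. Movement frames are those with 3D
#' fingertip speed of at least `eps_mm_s`; near-stationary frames are
#' excluded because sensor noise makes the sign of the projection
#' meaningless there. Frames with projection exactly zero count as
#' not-correct.
#'
#' @inheritParams estimate_velocity
#' @param eps_mm_s movement-frame speed threshold, mm/s.
#' @return percentage in `[0, 100]`, or `NA` (with a classed warning) when
#'   the trial has no movement frames.
#' @export
compute_rcm <- function(trial, finger = c("index", "middle"), eps_mm_s = 1) {
  finger <- match.arg(finger)
  k <- frame_kinematics(trial, finger, eps_mm_s)
  if (!any(k$moving)) {
    palp_warn("no movement frames: RCM undefined", "palp_undefined_metric")
    return(NA_real_)
  }
  100 * sum(k$vp[k$moving] > 0) / sum(k$moving)
}

#' Per-trial error rate
#'
#' Fraction of movement frames in which the fingertip's in-plane distance to
#' the target exceeds 30 mm (the error band). The denominator defaults to
#' movement frames, matching the frame-ratio convention of RCM; set
#' `denominator = "all"` to divide by every recorded frame instead.
#'
#' @inheritParams compute_rcm
#' @param denominator `"movement"` (default) or `"all"`.
#' @param error_radius_mm band boundary, mm.
#' @return ratio in `[0, 1]`, or `NA` (with a classed warning) when the
#'   denominator is empty.
#' @export
compute_error_rate <- function(trial, finger = c("index", "middle"),
                               eps_mm_s = 1,
                               denominator = c("movement", "all"),
                               error_radius_mm = 30) {
  finger <- match.arg(finger)
  denominator <- match.arg(denominator)
  k <- frame_kinematics(trial, finger, eps_mm_s)
  keep <- if (denominator == "movement") k$moving else rep(TRUE, length(k$moving))
  if (!any(keep)) {
    palp_warn("no movement frames: error rate undefined", "palp_undefined_metric")
    return(NA_real_)
  }
  sum(k$dist_plane[keep] > error_radius_mm) / sum(keep)
}

#' Compute the full metric set for one trial
#'
#' Evaluates all five objective skill metrics plus the accuracy band and the
#' binary within-30 mm outcome used by the accuracy model. Process metrics
#' (TPL, RCM, error rate) use the index fingertip by default.
#'
#' @inheritParams compute_error_rate
#' @return an object of class `metric_set`: a named list with
#'   `accuracy_mm`, `accuracy_band`, `accurate_binary`, `duration_s`,
#'   `tpl_mm`, `rcm_pct`, `error_rate`. Undefined frame-ratio metrics are
#'   `NA`.
#' @export
compute_metrics <- function(trial, finger = c("index", "middle"),
                            eps_mm_s = 1,
                            denominator = c("movement", "all")) {
  finger <- match.arg(finger)
  denominator <- match.arg(denominator)
  acc <- compute_accuracy(trial)
  band <- classify_accuracy(acc)
  structure(
    list(accuracy_mm = acc,
         accuracy_band = as.character(band),
         accurate_binary = acc <= 30,
         duration_s = compute_duration(trial),
         tpl_mm = compute_tpl(trial, finger),
         rcm_pct = compute_rcm(trial, finger, eps_mm_s),
         error_rate = compute_error_rate(trial, finger, eps_mm_s, denominator)),
    class = "metric_set"
  )
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf(
    "<metric_set> accuracy %.1f mm (%s), duration %.2f s, TPL %.0f mm, RCM %s, error rate %s\n",
    x$accuracy_mm, x$accuracy_band, x$duration_s, x$tpl_mm,
    if (is.na(x$rcm_pct)) "NA" else sprintf("%.1f%%", x$rcm_pct),
    if (is.na(x$error_rate)) "NA" else sprintf("%.3f", x$error_rate)))
  invisible(x)
}

#' Metric table for a set of trials
#'
#' One row per trial with identity, condition and all metric columns, the
#' interchange format consumed by the modeling functions and written by the
#' command-line pipeline.
#'
#' @param trials a list of [palp_trial()] objects.
#' @inheritParams compute_metrics
#' @return a data.frame with columns `trial_id`, `participant_id`,
#'   `vibration_type`, `vibration_intensity`, `skin_thickness_mm`,
#'   `location_index`, `accuracy_mm`, `accuracy_band`, `accurate_binary`,
#'   `duration_s`, `tpl_mm`, `rcm_pct`, `error_rate`.
#' @export
metrics_table <- function(trials, finger = c("index", "middle"),
                          eps_mm_s = 1,
                          denominator = c("movement", "all")) {
  finger <- match.arg(finger)
  denominator <- match.arg(denominator)
  rows <- lapply(trials, function(tr) {
    m <- compute_metrics(tr, finger, eps_mm_s, denominator)
    cbind(data.frame(trial_id = tr$trial_id,
                     participant_id = tr$participant_id,
                     vibration_type = tr$condition$vibration_type,
                     vibration_intensity = tr$condition$vibration_intensity,
                     skin_thickness_mm = tr$condition$skin_thickness_mm,
                     location_index = tr$condition$location_index,
                     stringsAsFactors = FALSE),
          as.data.frame(unclass(m), stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}
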