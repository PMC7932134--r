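#' Construct a haptic stimulus condition
#'
#' One cell of the 2 x 2 x 2 x 8 factorial of haptic stimulus factors used on
#' the palpation simulator: vibration type (an intermittent pulse versus the
#' continuous "thrill" felt over a healthy arteriovenous fistula), vibration
#' intensity, artificial-skin thickness, and which of 8 simulator positions
#' hides the vibration source.
#'
#' @param vibration_type `"pulse"` or `"thrill"`.
#' @param vibration_intensity `"strong"` or `"weak"`.
#' @param skin_thickness_mm `4` or `6` (millimeters).
#' @param location_index integer in `1..8`.
#' @return an object of class `haptic_condition`.
#' @export
#' @examples
#' haptic_condition("thrill", "strong", 4, 1)
haptic_condition <- function(vibration_type, vibration_intensity,
                             skin_thickness_mm, location_index) {
  if (!is.character(vibration_type) || length(vibration_type) != 1L ||
      !vibration_type %in% c("pulse", "thrill")) {
    palp_error("vibration_type must be \"pulse\" or \"thrill\"", "palp_domain_error")
  }
  if (!is.character(vibration_intensity) || length(vibration_intensity) != 1L ||
      !vibration_intensity %in% c("strong", "weak")) {
    palp_error("vibration_intensity must be \"strong\" or \"weak\"", "palp_domain_error")
  }
  if (length(skin_thickness_mm) != 1L || !skin_thickness_mm %in% c(4, 6)) {
    palp_error("skin_thickness_mm must be 4 or 6", "palp_domain_error")
  }
  if (length(location_index) != 1L || is.na(location_index) ||
      location_index != as.integer(location_index) ||
      location_index < 1L || location_index > 8L) {
    palp_error("location_index must be an integer in 1..8", "palp_domain_error")
  }
  structure(
    list(vibration_type = vibration_type,
         vibration_intensity = vibration_intensity,
         skin_thickness_mm = as.numeric(skin_thickness_mm),
         location_index = as.integer(location_index)),
    class = "haptic_condition"
  )
}

#' Canonical target coordinates for a simulator location index
#'
#' The simulator presents the vibration source at one of 8 positions obtained
#' by rotating the octagonal box. The physical coordinates are not part of the
#' study design, so this package adopts an explicit convention: 8 points
#' evenly spaced on a circle of radius 50 mm about the workspace origin, index
#' 1 at angle 0 (positive x axis), proceeding counterclockwise.
#'
#' @param location_index integer in `1..8`.
#' @param ring_radius_mm radius of the target ring; default 50.
#' @return numeric `c(x_mm, y_mm)`.
#' @export
#' @examples
#' target_position(1)  # c(50, 0)
#' target_position(3)  # c(0, 50)
target_position <- function(location_index, ring_radius_mm = 50) {
  if (length(location_index) != 1L || is.na(location_index) ||
      location_index != as.integer(location_index) ||
      location_index < 1L || location_index > 8L) {
    palp_error("location_index must be an integer in 1..8", "palp_domain_error")
  }
  theta <- (as.integer(location_index) - 1L) * pi / 4
  p <- c(x_mm = ring_radius_mm * cos(theta), y_mm = ring_radius_mm * sin(theta))
  # exact zeros at the four axis-aligned positions
  p[abs(p) < 1e-12] <- 0
  p
}

#' Construct a validated palpation trial
#'
#' Bundles one trial's fingertip trajectory (timestamped 3D positions of the
#' index and middle fingertips, millimeters and seconds) with its stimulus
#' condition, participant, and true target location in the skin plane. The
#' coordinate frame is right-handed with x-y the skin plane and z the height
#' above the skin; the origin is the workspace (octagon) center.
#'
#' @param trial_id,participant_id character scalars.
#' @param condition a [haptic_condition()].
#' @param target numeric `c(x, y)` target point in the skin plane, mm;
#'   must lie within the 100 mm workspace disc.
#' @param frames data.frame with columns `t_s, ix, iy, iz, mx, my, mz`:
#'   time since trial start (s) and index/middle fingertip coordinates (mm).
#'   At least 2 rows; `t_s` strictly increasing; all values finite.
#' @return an object of class `palp_trial`.
#' @export
palp_trial <- function(trial_id, participant_id, condition, target, frames) {
  if (!is.character(trial_id) || length(trial_id) != 1L || !nzchar(trial_id)) {
    palp_error("trial_id must be a non-empty string", "palp_domain_error")
  }
  if (!is.character(participant_id) || length(participant_id) != 1L ||
      !nzchar(participant_id)) {
    palp_error("participant_id must be a non-empty string", "palp_domain_error")
  }
  if (!inherits(condition, "haptic_condition")) {
    palp_error("condition must be a haptic_condition", "palp_domain_error")
  }
  target <- as.numeric(target)
  if (length(target) != 2L || !all(is.finite(target))) {
    palp_error("target must be finite c(x, y) in mm", "palp_domain_error")
  }
  if (sqrt(sum(target^2)) > 100 + 1e-9) {
    palp_error("target lies outside the 100 mm workspace disc", "palp_domain_error")
  }
  frames <- validate_frames(frames)
  structure(
    list(trial_id = trial_id, participant_id = participant_id,
         condition = condition,
         target = c(x_mm = target[[1L]], y_mm = target[[2L]]),
         frames = frames),
    class = "palp_trial"
  )
}

frame_columns <- c("t_s", "ix", "iy", "iz", "mx", "my", "mz")

validate_frames <- function(frames) {
  if (!is.data.frame(frames)) {
    palp_error("frames must be a data.frame", "palp_format_error")
  }
  missing_cols <- setdiff(frame_columns, names(frames))
  if (length(missing_cols)) {
    palp_error(paste0("frames missing column(s): ",
                      paste(missing_cols, collapse = ", ")),
               "palp_format_error")
  }
  frames <- frames[frame_columns]
  for (cl in frame_columns) frames[[cl]] <- as.numeric(frames[[cl]])
  if (nrow(frames) < 2L) {
    palp_error("a trial needs at least 2 frames", "palp_degenerate_trial")
  }
  if (!all(vapply(frames, function(x) all(is.finite(x)), logical(1L)))) {
    palp_error("frames contain non-finite values", "palp_malformed_input")
  }
  if (frames$t_s[1L] < 0) {
    palp_error("timestamps must be >= 0", "palp_malformed_input")
  }
  if (any(diff(frames$t_s) <= 0)) {
    palp_error("timestamps must be strictly increasing", "palp_malformed_input")
  }
  rownames(frames) <- NULL
  frames
}

#' @export
print.palp_trial <- function(x, ...) {
  cat(sprintf("<palp_trial %s> participant %s, %d frames over %.3f s\n",
              x$trial_id, x$participant_id, nrow(x$frames),
              x$frames$t_s[nrow(x$frames)] - x$frames$t_s[1L]))
  cat(sprintf("  condition: %s / %s / %g mm skin / location %d\n",
              x$condition$vibration_type, x$condition$vibration_intensity,
              x$condition$skin_thickness_mm, x$condition$location_index))
  cat(sprintf("  target: (%.1f, %.1f) mm\n", x$target[1L], x$target[2L]))
  invisible(x)
}

#' Read a trial from a frame CSV plus manifest entry
#'
#' The frame CSV has header `t_s,ix,iy,iz,mx,my,mz` (comma separated, `.`
#' decimal, UTF-8, no index column). The manifest entry supplies identity,
#' condition and target. Rows are validated, never silently re-sorted.
#'
#' @param frame_csv_path path to the frame CSV.
#' @param manifest_entry list (or one-row data.frame) with fields `trial_id`,
#'   `participant_id`, `vibration_type`, `vibration_intensity`,
#'   `skin_thickness_mm`, `location_index`, `target_x_mm`, `target_y_mm`.
#' @return a [palp_trial()].
#' @export
read_trial <- function(frame_csv_path, manifest_entry) {
  if (!file.exists(frame_csv_path)) {
    palp_error(paste0("no such frame file: ", frame_csv_path), "palp_io_error")
  }
  m <- as.list(manifest_entry)
  need <- c("trial_id", "participant_id", "vibration_type", "vibration_intensity",
            "skin_thickness_mm", "location_index", "target_x_mm", "target_y_mm")
  if (length(setdiff(need, names(m)))) {
    palp_error(paste0("manifest entry missing field(s): ",
                      paste(setdiff(need, names(m)), collapse = ", ")),
               "palp_format_error")
  }
  frames <- tryCatch(
    utils::read.csv(frame_csv_path, colClasses = "numeric", check.names = TRUE),
    error = function(e) {
      palp_error(paste0("cannot parse frame CSV ", frame_csv_path, ": ",
                        conditionMessage(e)), "palp_format_error")
    })
  cond <- haptic_condition(as.character(m$vibration_type),
                           as.character(m$vibration_intensity),
                           as.numeric(m$skin_thickness_mm),
                           as.integer(m$location_index))
  palp_trial(as.character(m$trial_id), as.character(m$participant_id),
             cond, c(as.numeric(m$target_x_mm), as.numeric(m$target_y_mm)),
             frames)
}

#' Write a trial's frames to CSV
#'
#' Writes the fixed column order `t_s,ix,iy,iz,mx,my,mz` at full double
#' precision (17 significant digits), so write/read round-trips are
#' bit-identical and identical trials produce identical bytes.
#'
#' @param trial a [palp_trial()].
#' @param frame_csv_path output path.
#' @return invisibly, the path written.
#' @export
write_trial <- function(trial, frame_csv_path) {
  if (!inherits(trial, "palp_trial")) {
    palp_error("trial must be a palp_trial", "palp_domain_error")
  }
  dir <- dirname(frame_csv_path)
  if (!dir.exists(dir)) {
    palp_error(paste0("directory does not exist: ", dir), "palp_io_error")
  }
  fr <- trial$frames
  lines <- c(paste(frame_columns, collapse = ","),
             do.call(paste, c(lapply(fr, function(x) {
               sprintf("%.17g", x)
             }), sep = ",")))
  con <- file(frame_csv_path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(frame_csv_path)
}

#' Manifest entry for a trial
#'
#' @param trial a [palp_trial()].
#' @param frame_file relative path of the trial's frame CSV.
#' @return a one-row data.frame matching the study manifest schema.
#' @keywords internal
manifest_entry <- function(trial, frame_file) {
  data.frame(trial_id = trial$trial_id,
             participant_id = trial$participant_id,
             vibration_type = trial$condition$vibration_type,
             vibration_intensity = trial$condition$vibration_intensity,
             skin_thickness_mm = trial$condition$skin_thickness_mm,
             location_index = trial$condition$location_index,
             target_x_mm = unname(trial$target[1L]),
             target_y_mm = unname(trial$target[2L]),
             frame_file = frame_file,
             stringsAsFactors = FALSE)
}
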