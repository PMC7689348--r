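# Time-series containers: synchronized marker positions, gaze samples, and
# the per-trial recording bundle.

#' Marker position series
#'
#' @param times strictly increasing sample times, seconds from trial start.
#' @param positions named list of n x 3 matrices (meters, room frame), one per
#'   marker. All share the time axis.
#' @param rate nominal sampling rate, Hz.
#' @param validate skip validation in trusted hot paths.
#' @return an object of class `marker_series`.
#' @export
marker_series <- function(times, positions, rate = 120, validate = TRUE) {
  if (validate) {
    times <- as.numeric(times)
    if (length(times) < 2L || any(diff(times) <= 0)) {
      stop_nav("marker times must be strictly increasing (length >= 2)")
    }
    if (is.null(names(positions)) || any(!nzchar(names(positions)))) {
      stop_nav("positions must be a named list of matrices")
    }
    positions <- lapply(positions, function(m) {
      m <- as.matrix(m); storage.mode(m) <- "double"; m
    })
    bad <- names(positions)[vapply(positions, function(m)
      nrow(m) != length(times) || ncol(m) != 3L, logical(1))]
    if (length(bad) > 0) {
      stop_nav("markers not on the shared time axis (need n x 3): ",
               paste(bad, collapse = ", "))
    }
    if (!is.numeric(rate) || rate <= 0) stop_nav("rate must be > 0")
  }
  structure(list(times = times, positions = positions, rate = rate),
            class = "marker_series")
}

# canonical marker labels used by the analysis
HEEL_LEFT <- "left_heel"
HEEL_RIGHT <- "right_heel"
EYE_FRAME <- c("eye_frame_1", "eye_frame_2", "eye_frame_3", "eye_frame_4")

require_markers <- function(markers, labels) {
  missing <- setdiff(labels, names(markers$positions))
  if (length(missing) > 0) {
    pretty <- gsub("_", " ", missing)
    stop_nav("recording is missing required marker(s): ",
             paste(pretty, collapse = ", "))
  }
  invisible(TRUE)
}

#' Centroid of the four eye-tracker-frame markers
#'
#' This centroid is the body reference point of the analysis: its horizontal
#' velocity defines heading, and its horizontal projection defines per-step
#' speed, the walked trajectory, and the goal-border crossing.
#'
#' @param markers a `marker_series` containing the four eye-frame markers.
#' @return n x 3 matrix.
#' @export
eye_frame_centroid <- function(markers) {
  require_markers(markers, EYE_FRAME)
  (markers$positions[[EYE_FRAME[1]]] + markers$positions[[EYE_FRAME[2]]] +
     markers$positions[[EYE_FRAME[3]]] + markers$positions[[EYE_FRAME[4]]]) / 4
}

#' Gaze sample series
#'
#' @param times sample times, seconds; strictly increasing.
#' @param origins n x 3 matrix of gaze origins (eye position), meters.
#' @param directions n x 3 matrix of unit gaze direction vectors.
#' @param rate nominal rate, Hz (60 before resampling).
#' @param valid optional logical vector; `FALSE` marks samples that must not
#'   be used (tracking loss).
#' @param validate skip validation in trusted hot paths.
#' @return an object of class `gaze_series`.
#' @export
gaze_series <- function(times, origins, directions, rate = 60, valid = NULL,
                        validate = TRUE) {
  n <- length(times)
  if (is.null(valid)) valid <- rep(TRUE, n)
  if (validate) {
    times <- as.numeric(times)
    if (n < 1L || (n > 1L && any(diff(times) <= 0))) {
      stop_nav("gaze times must be strictly increasing")
    }
    origins <- as.matrix(origins); directions <- as.matrix(directions)
    if (nrow(origins) != n || nrow(directions) != n ||
        ncol(origins) != 3L || ncol(directions) != 3L) {
      stop_nav("origins and directions must be n x 3 matrices on the time axis")
    }
    nrm <- row_norms(directions[valid, , drop = FALSE])
    if (length(nrm) > 0 && max(abs(nrm - 1)) > 1e-9) {
      stop_nav("gaze directions must be unit vectors (max |norm-1| = ",
               signif(max(abs(nrm - 1)), 3), ")")
    }
    if (!is.numeric(rate) || rate <= 0) stop_nav("rate must be > 0")
  }
  structure(list(times = times, origins = origins, directions = directions,
                 rate = rate, valid = valid),
            class = "gaze_series")
}

#' Bundle one trial's synchronized data and metadata
#'
#' @param participant_id participant identifier.
#' @param group `"young"` or `"older"`.
#' @param trial_index 1-based trial number.
#' @param start_position 2D start position, meters.
#' @param markers a `marker_series`.
#' @param gaze a `gaze_series`, or `NULL` for kinematics-only recordings.
#' @param trial_end_time time (s) at which the trajectory first crossed the
#'   goal-zone border; `NA` to have the analysis detect it.
#' @return an object of class `trial_recording`.
#' @export
trial_recording <- function(participant_id, group, trial_index, start_position,
                            markers, gaze = NULL, trial_end_time = NA_real_) {
  group <- match.arg(group, c("young", "older"))
  trial_index <- as.integer(trial_index)
  if (is.na(trial_index) || trial_index < 1L) stop_nav("trial_index must be >= 1")
  stopifnot(inherits(markers, "marker_series"))
  if (!is.null(gaze)) stopifnot(inherits(gaze, "gaze_series"))
  if (!is.na(trial_end_time)) {
    rng <- range(markers$times)
    if (trial_end_time < rng[1] - 1e-9 || trial_end_time > rng[2] + 1e-9) {
      stop_nav("trial_end_time (", trial_end_time,
               " s) lies outside the recorded time span")
    }
  }
  structure(list(participant_id = as.character(participant_id), group = group,
                 trial_index = trial_index,
                 start_position = as.numeric(start_position),
                 markers = markers, gaze = gaze,
                 trial_end_time = trial_end_time),
            class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  cat("<trial_recording> participant ", x$participant_id, " (", x$group,
      "), trial ", x$trial_index, ": ", length(x$markers$times),
      " marker samples @", x$markers$rate, " Hz",
      if (!is.null(x$gaze)) paste0(", ", length(x$gaze$times), " gaze samples @",
                                   x$gaze$rate, " Hz"),
      ", end ", signif(x$trial_end_time, 4), " s\n", sep = "")
  invisible(x)
}
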