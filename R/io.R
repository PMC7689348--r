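# Recording I/O: a plain, inspectable delimited dialect.
#
# A recording is stored as up to three files sharing a stem:
#   <stem>_markers.csv  one row per sample: time, <marker>_x, _y, _z, ...
#   <stem>_gaze.csv     time, origin_{x,y,z}, dir_{x,y,z}, valid
#   <stem>_meta.json    participant, group, trial index, start pose, units,
#                       rates, trial end time
# Units are meters/seconds unless meta declares "mm" (converted on read).

#' Write a trial recording to delimited files
#'
#' @param rec a `trial_recording`.
#' @param stem path stem; `_markers.csv`, `_gaze.csv` (when gaze is present)
#'   and `_meta.json` are appended.
#' @return `stem`, invisibly.
#' @export
write_recording <- function(rec, stem) {
  stopifnot(inherits(rec, "trial_recording"))
  mk <- rec$markers
  df <- data.frame(time = mk$times)
  for (nm in names(mk$positions)) {
    p <- mk$positions[[nm]]
    df[[paste0(nm, "_x")]] <- p[, 1]
    df[[paste0(nm, "_y")]] <- p[, 2]
    df[[paste0(nm, "_z")]] <- p[, 3]
  }
  utils::write.csv(df, paste0(stem, "_markers.csv"), row.names = FALSE)
  if (!is.null(rec$gaze)) {
    g <- rec$gaze
    gdf <- data.frame(time = g$times,
                      origin_x = g$origins[, 1], origin_y = g$origins[, 2],
                      origin_z = g$origins[, 3],
                      dir_x = g$directions[, 1], dir_y = g$directions[, 2],
                      dir_z = g$directions[, 3],
                      valid = as.integer(g$valid))
    utils::write.csv(gdf, paste0(stem, "_gaze.csv"), row.names = FALSE)
  }
  meta <- list(participant_id = rec$participant_id, group = rec$group,
               trial_index = rec$trial_index,
               start_position = rec$start_position,
               trial_end_time = rec$trial_end_time,
               marker_rate = rec$markers$rate,
               gaze_rate = if (!is.null(rec$gaze)) rec$gaze$rate else NULL,
               units = "m")
  jsonlite::write_json(meta, paste0(stem, "_meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(stem)
}

#' Read a trial recording
#'
#' @param stem path stem used by [write_recording()].
#' @param format `"delimited"`; `"c3d"` is recognized but not supported by
#'   this implementation and raises an informative error.
#' @return a `trial_recording`.
#' @export
read_recording <- function(stem, format = c("delimited", "c3d")) {
  format <- match.arg(format)
  if (format == "c3d") {
    stop_nav("C3D input is not supported by this build; export the recording ",
             "to the delimited dialect (see write_recording)")
  }
  mpath <- paste0(stem, "_markers.csv")
  if (!file.exists(mpath)) stop_nav("marker file not found: ", mpath)
  meta_path <- paste0(stem, "_meta.json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list()
  scale <- if (identical(meta$units, "mm")) 1e-3 else 1
  df <- utils::read.csv(mpath, check.names = FALSE)
  if (!"time" %in% names(df)) stop_nav("marker file lacks a 'time' column")
  times <- as.numeric(df$time)
  if (any(diff(times) <= 0)) stop_nav("non-monotone time axis in ", mpath)
  coord_cols <- grep("_(x|y|z)$", names(df), value = TRUE)
  labels <- unique(sub("_(x|y|z)$", "", coord_cols))
  positions <- lapply(labels, function(nm) {
    cols <- paste0(nm, c("_x", "_y", "_z"))
    if (!all(cols %in% names(df))) {
      stop_nav("marker '", gsub("_", " ", nm), "' lacks one of the _x/_y/_z columns")
    }
    as.matrix(df[, cols]) * scale
  })
  names(positions) <- labels
  markers <- marker_series(times, positions, rate = meta$marker_rate %||%
                             (1 / stats::median(diff(times))))
  require_markers(markers, c(HEEL_LEFT, HEEL_RIGHT, EYE_FRAME))
  gaze <- NULL
  gpath <- paste0(stem, "_gaze.csv")
  if (file.exists(gpath)) {
    gdf <- utils::read.csv(gpath)
    gaze <- gaze_series(as.numeric(gdf$time),
                        as.matrix(gdf[, c("origin_x", "origin_y", "origin_z")]) * scale,
                        as.matrix(gdf[, c("dir_x", "dir_y", "dir_z")]),
                        rate = meta$gaze_rate %||% (1 / stats::median(diff(gdf$time))),
                        valid = as.logical(gdf$valid %||% TRUE))
  }
  trial_recording(meta$participant_id %||% "unknown",
                  meta$group %||% "young",
                  meta$trial_index %||% 1L,
                  as.numeric(meta$start_position %||% c(NA_real_, NA_real_)),
                  markers, gaze,
                  trial_end_time = as.numeric(meta$trial_end_time %||% NA_real_))
}
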