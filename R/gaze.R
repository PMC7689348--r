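# Gaze processing: resampling onto the marker time base, ray intersection
# with the room model, dispersion-based fixation detection, and goal-area
# classification.

#' Resample a gaze series to a target rate
#'
#' Origins are interpolated linearly and directions by spherical linear
#' interpolation (slerp), so interpolated directions stay unit-norm. Target
#' samples bracketed by a gaze gap longer than `max_gap`, bracketed by an
#' invalid source sample, or outside the recorded span are flagged invalid,
#' never interpolated.
#'
#' @param gaze a `gaze_series`.
#' @param target_rate target rate, Hz (120 by default, the marker rate).
#' @param target_times optional explicit time base (e.g. the marker times);
#'   overrides `target_rate`.
#' @param max_gap longest source gap that may be interpolated across, s.
#' @return a `gaze_series` on the new time base.
#' @export
resample_gaze <- function(gaze, target_rate = 120, target_times = NULL,
                          max_gap = 0.2) {
  stopifnot(inherits(gaze, "gaze_series"))
  if (target_rate <= 0) stop_nav("target_rate must be > 0")
  tt <- target_times %||%
    seq(gaze$times[1], gaze$times[length(gaze$times)], by = 1 / target_rate)
  ts <- gaze$times
  n <- length(ts)
  i0 <- findInterval(tt, ts)
  inside <- i0 >= 1L & i0 < n
  exact_end <- i0 == n & abs(tt - ts[n]) < 1e-9
  i0[!inside] <- 1L  # placeholder, masked below
  i1 <- i0 + 1L
  w <- (tt - ts[i0]) / (ts[i1] - ts[i0])
  valid <- inside & (ts[i1] - ts[i0]) <= max_gap &
    gaze$valid[i0] & gaze$valid[i1]
  org <- (1 - w) * gaze$origins[i0, , drop = FALSE] +
    w * gaze$origins[i1, , drop = FALSE]
  dirs <- slerp_rows(gaze$directions[i0, , drop = FALSE],
                     gaze$directions[i1, , drop = FALSE], w)
  if (any(exact_end)) {
    org[exact_end, ] <- gaze$origins[rep(n, sum(exact_end)), , drop = FALSE]
    dirs[exact_end, ] <- gaze$directions[rep(n, sum(exact_end)), , drop = FALSE]
    valid[exact_end] <- gaze$valid[n]
  }
  valid[!(inside | exact_end)] <- FALSE
  gaze_series(tt, org, dirs, rate = 1 / stats::median(diff(tt)), valid = valid,
              validate = FALSE)
}

# spherical interpolation between paired rows of unit vectors
slerp_rows <- function(d0, d1, w) {
  dot <- pmin(pmax(rowSums(d0 * d1), -1), 1)
  omega <- acos(dot)
  small <- omega < 1e-6
  s <- sin(omega)
  s[small] <- 1  # avoid 0/0; handled by linear branch below
  a <- sin((1 - w) * omega) / s
  b <- sin(w * omega) / s
  a[small] <- 1 - w[small]
  b[small] <- w[small]
  out <- a * d0 + b * d1
  out / row_norms(out)
}

#' Intersect gaze rays with the environment
#'
#' For every sample the nearest forward intersection of the gaze ray with the
#' environment's surfaces is computed; samples whose ray hits nothing (or
#' that are invalid in the input) are flagged invalid.
#'
#' @param gaze a `gaze_series` (typically resampled to the marker rate).
#' @param env a `nav_environment`.
#' @return an object of class `gaze_points`: list with `times`, `points`
#'   (n x 3), `surface_id` (character), `valid` (logical).
#' @export
intersect_gaze <- function(gaze, env) {
  stopifnot(inherits(gaze, "gaze_series"), inherits(env, "nav_environment"))
  n <- length(gaze$times)
  best_t <- rep(Inf, n)
  surface_id <- rep(NA_character_, n)
  pts <- matrix(NA_real_, n, 3)
  o <- gaze$origins; d <- gaze$directions
  for (s in env$surfaces) {
    denom <- d %*% s$normal
    offs <- (matrix(s$origin, n, 3, byrow = TRUE) - o) %*% s$normal
    tt <- as.numeric(offs) / as.numeric(denom)
    cand <- is.finite(tt) & tt > 1e-9 & tt < best_t
    if (!any(cand)) next
    px <- o[cand, 1] + tt[cand] * d[cand, 1]
    py <- o[cand, 2] + tt[cand] * d[cand, 2]
    pz <- o[cand, 3] + tt[cand] * d[cand, 3]
    pm <- cbind(px, py, pz)
    inside <- points_in_polygon(pm[, s$proj_axes[1]], pm[, s$proj_axes[2]],
                                s$poly2d)
    if (!any(inside)) next
    idx <- which(cand)[inside]
    best_t[idx] <- tt[idx]
    surface_id[idx] <- s$id
    pts[idx, ] <- pm[inside, , drop = FALSE]
  }
  valid <- gaze$valid & is.finite(best_t)
  surface_id[!valid] <- NA_character_
  pts[!valid, ] <- NA_real_
  structure(list(times = gaze$times, points = pts, surface_id = surface_id,
                 valid = valid),
            class = "gaze_points")
}

#' Gaze dispersion series
#'
#' Euclidean distance, in the room frame, between successive gaze
#' intersection points. Pairs involving an invalid sample are undefined.
#'
#' @param points a `gaze_points` object.
#' @return numeric vector of length n-1; `NA` where undefined.
#' @export
dispersion_series <- function(points) {
  n <- length(points$times)
  if (n < 2L) stop_nav("need at least two samples for a dispersion series")
  p <- points$points
  d <- sqrt(rowSums((p[-1L, , drop = FALSE] - p[-n, , drop = FALSE])^2))
  d[!(points$valid[-n] & points$valid[-1L])] <- NA_real_
  d
}

#' Detect fixations by dispersion threshold
#'
#' The per-trial threshold is `median(d) + dispersion_k * IQR(d)` over all
#' defined dispersion values; maximal runs of consecutive dispersions
#' strictly below the threshold, lasting at least `min_fixation`
#' milliseconds, become fixations. Invalid samples break candidate runs.
#'
#' @param points a `gaze_points` object.
#' @param cfg an [analysis_config()].
#' @return data frame with one row per fixation: `t_start`, `t_end`,
#'   `duration_ms`, centroid `x`, `y`, `z`, dominant `surface_id`,
#'   `in_goal_area` (`NA` until classified).
#' @export
detect_fixations <- function(points, cfg = analysis_config()) {
  empty <- data.frame(t_start = numeric(0), t_end = numeric(0),
                      duration_ms = numeric(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), surface_id = character(0),
                      in_goal_area = logical(0))
  d <- dispersion_series(points)
  if (sum(!is.na(d)) < 10L) {
    warning("too few valid gaze samples to estimate a dispersion threshold")
    return(empty)
  }
  thr <- fixation_threshold(d, cfg$dispersion_k)
  # strictly below the threshold; values at or below the median also count,
  # which matters only when the dispersion distribution is degenerate (a
  # perfectly stationary trace has threshold 0)
  med <- stats::median(d[!is.na(d)])
  below <- !is.na(d) & (d < thr | d <= med)
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rows <- list()
  tms <- points$times
  for (k in which(r$values)) {
    i <- starts[k]; j <- ends[k]          # dispersion indices -> samples i..j+1
    t0 <- tms[i]; t1 <- tms[j + 1L]
    if ((t1 - t0) * 1000 < cfg$min_fixation) next
    idx <- i:(j + 1L)
    ctr <- colMeans(points$points[idx, , drop = FALSE])
    tab <- table(points$surface_id[idx])
    dom <- if (length(tab) > 0) names(tab)[which.max(tab)] else NA_character_
    rows[[length(rows) + 1L]] <- data.frame(
      t_start = t0, t_end = t1, duration_ms = (t1 - t0) * 1000,
      x = ctr[1], y = ctr[2], z = ctr[3], surface_id = dom,
      in_goal_area = NA)
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

fixation_threshold <- function(d, k) {
  d <- d[!is.na(d)]
  stats::median(d) + k * stats::IQR(d)
}

#' Classify goal-area fixations
#'
#' A fixation is in the goal area when its dominant surface belongs to the
#' environment's goal-area surface set; fixations on (near-)horizontal
#' goal-area surfaces (the floor) must additionally land inside the
#' configured goal-area floor polygon.
#'
#' @param fixs fixation table from [detect_fixations()].
#' @param env a `nav_environment`.
#' @return the same table with `in_goal_area` set.
#' @export
classify_goal_fixations <- function(fixs, env) {
  if (nrow(fixs) == 0L) return(fixs)
  in_set <- fixs$surface_id %in% env$goal_area_surface_ids
  floor_ids <- vapply(env$surfaces, function(s) {
    if (abs(s$normal[3]) > 0.99) s$id else NA_character_
  }, character(1))
  floor_ids <- floor_ids[!is.na(floor_ids)]
  on_floor <- fixs$surface_id %in% floor_ids
  in_poly <- points_in_polygon(fixs$x, fixs$y, env$goal_floor_polygon)
  fixs$in_goal_area <- in_set & (!on_floor | in_poly)
  fixs$in_goal_area[is.na(fixs$surface_id)] <- FALSE
  fixs
}

#' Proportion of fixations directed toward the goal area
#'
#' @param fixs classified fixation table.
#' @return proportion in \[0, 1\]; `NA` with a warning when there are no
#'   fixations.
#' @export
goal_fixation_proportion <- function(fixs) {
  if (nrow(fixs) == 0L) {
    warning(warningCondition("no fixations: goal-fixation proportion undefined",
                             class = "navpace_no_fixations"))
    return(NA_real_)
  }
  mean(fixs$in_goal_area)
}
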