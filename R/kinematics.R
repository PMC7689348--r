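# Kinematics: zero-phase low-pass filtering, heel-strike detection from the
# vertical heel velocity, standing periods, orientation/navigation phases,
# heading of the body reference point, step segmentation and classification,
# and the per-trial walking speed.

#' Zero-phase Butterworth low-pass filter
#'
#' Designs a Butterworth low-pass filter and applies it forward and backward
#' (zero phase). The input is padded by odd reflection at both ends so that
#' start-up transients die out outside the returned span; a constant signal
#' is returned unchanged to numerical precision.
#'
#' @param x a `marker_series`, a numeric vector, or an n x k matrix of
#'   signals sampled at `rate`.
#' @param cutoff cutoff frequency, Hz.
#' @param order filter order (the effective attenuation is that of twice the
#'   order because of the two passes).
#' @param rate sampling rate, Hz (taken from the series when `x` is a
#'   `marker_series`).
#' @return an object of the same shape as `x` with every signal filtered;
#'   time axes are unchanged.
#' @export
lowpass <- function(x, cutoff = 10, order = 2, rate = NULL) {
  UseMethod("lowpass")
}

#' @export
lowpass.marker_series <- function(x, cutoff = 10, order = 2, rate = NULL) {
  rate <- rate %||% x$rate
  ba <- butter_coef(cutoff, order, rate)
  x$positions <- lapply(x$positions, function(p) {
    apply_zerophase(p, ba$b, ba$a, rate, cutoff)
  })
  x
}

#' @export
lowpass.default <- function(x, cutoff = 10, order = 2, rate = NULL) {
  if (is.null(rate)) stop_nav("rate is required when filtering raw signals")
  ba <- butter_coef(cutoff, order, rate)
  apply_zerophase(x, ba$b, ba$a, rate, cutoff)
}

butter_coef <- function(cutoff, order, rate) {
  if (rate <= 2 * cutoff) {
    stop_nav("sampling rate (", rate, " Hz) must exceed twice the cutoff (",
             cutoff, " Hz)")
  }
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  list(b = bf$b, a = bf$a)
}

apply_zerophase <- function(x, b, a, rate, cutoff) {
  if (is.matrix(x)) {
    for (j in seq_len(ncol(x))) x[, j] <- zerophase_one(x[, j], b, a, rate, cutoff)
    return(x)
  }
  zerophase_one(x, b, a, rate, cutoff)
}

zerophase_one <- function(x, b, a, rate, cutoff) {
  n <- length(x)
  pad <- max(24L, ceiling(8 * rate / cutoff))
  if (n <= max(12L, 3 * length(a))) {
    stop_nav("series too short for filter warm-up (", n, " samples)")
  }
  pad <- min(pad, n - 1L)
  front <- 2 * x[1] - x[seq(pad + 1L, 2L)]
  back <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  xp <- c(front, x, back)
  y <- iir_filter(b, a, xp)
  y <- rev(iir_filter(b, a, rev(y)))
  as.numeric(y[(pad + 1L):(pad + n)])
}

# direct-form IIR pass: numerator by convolution, denominator recursively
iir_filter <- function(b, a, x) {
  v <- stats::filter(c(rep(x[1], length(b) - 1L), x), b, method = "convolution",
                     sides = 1)
  v <- v[-seq_len(length(b) - 1L)]
  if (length(a) > 1L) {
    v <- stats::filter(v, -a[-1L], method = "recursive")
  }
  as.numeric(v)
}

# zero-phase filtering of the columns of a matrix in batched filter calls
zerophase_mat <- function(xm, b, a, rate, cutoff) {
  n <- nrow(xm)
  pad <- max(24L, ceiling(8 * rate / cutoff))
  if (n <= max(12L, 3 * length(a))) {
    stop_nav("series too short for filter warm-up (", n, " samples)")
  }
  pad <- min(pad, n - 1L)
  k <- ncol(xm)
  refl <- function(edge, idx) 2 * xm[rep(edge, pad), , drop = FALSE] -
    xm[idx, , drop = FALSE]
  xp <- rbind(refl(1L, seq(pad + 1L, 2L)), xm,
              refl(n, seq(n - 1L, n - pad)))
  pass <- function(m) {
    nb <- length(b) - 1L
    v <- stats::filter(rbind(m[rep(1L, nb), , drop = FALSE], m), b,
                       method = "convolution", sides = 1)
    v <- matrix(as.numeric(v), ncol = k)[-seq_len(nb), , drop = FALSE]
    if (length(a) > 1L) {
      v <- matrix(as.numeric(stats::filter(v, -a[-1L], method = "recursive")),
                  ncol = k)
    }
    v
  }
  y <- pass(xp)
  y <- pass(y[rev(seq_len(nrow(y))), , drop = FALSE])
  y[rev(seq_len(nrow(y))), , drop = FALSE][(pad + 1L):(pad + n), , drop = FALSE]
}

#' Central-difference velocity
#'
#' @param times sample times, s.
#' @param x numeric vector or n x k matrix (one signal per column).
#' @return object shaped like `x` with the time derivative; one-sided
#'   differences at the ends.
#' @export
velocity <- function(times, x) {
  n <- length(times)
  if (n < 2L) stop_nav("need at least two samples to differentiate")
  deriv1 <- function(v) {
    d <- numeric(n)
    d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (times[3:n] - times[1:(n - 2)])
    d[1] <- (v[2] - v[1]) / (times[2] - times[1])
    d[n] <- (v[n] - v[n - 1]) / (times[n] - times[n - 1])
    d
  }
  if (is.matrix(x)) {
    out <- x
    for (j in seq_len(ncol(x))) out[, j] <- deriv1(x[, j])
    out
  } else deriv1(x)
}

#' Detect heel strikes from the vertical heel trajectory
#'
#' A strike is a downward-to-upward sign change of the vertical heel
#' velocity. Candidate crossings survive three cleaning rules: the preceding
#' downward swing must reach a peak downward velocity of at least
#' `strike_min_downswing`; events inside detected standing intervals are
#' discarded; and a per-foot refractory period keeps only the first event of
#' any cluster.
#'
#' @param times sample times, s (filtered input assumed).
#' @param z vertical heel position, m; ignored when `vz` is supplied.
#' @param foot `"left"` or `"right"`.
#' @param cfg an [analysis_config()].
#' @param standing optional data frame of standing intervals
#'   (`t_start`, `t_end`) used to suppress spurious events.
#' @param vz optional precomputed vertical velocity, m/s.
#' @return data frame with columns `time`, `foot`, ordered by time.
#' @export
detect_heel_strikes <- function(times, z = NULL, foot = c("left", "right"),
                                cfg = analysis_config(), standing = NULL,
                                vz = NULL) {
  foot <- match.arg(foot)
  if (is.null(vz)) {
    if (is.null(z)) stop_nav("supply z or vz")
    if (length(z) < 3L) {
      return(data.frame(time = numeric(0), foot = character(0)))
    }
    vz <- velocity(times, z)
  }
  ev <- strike_times_impl(times, vz, cfg, standing)
  data.frame(time = ev, foot = rep(foot, length(ev)))
}

# vector core of detect_heel_strikes (shared by the per-trial hot path)
strike_times_impl <- function(times, vz, cfg, standing = NULL) {
  n <- length(vz)
  if (n < 2L) return(numeric(0))
  pos <- vz > 0
  # boundaries of non-positive runs followed by a positive sample
  ends <- which(!pos[-n] & pos[-1L])
  if (length(ends) == 0L) return(numeric(0))
  # start of each non-positive run (rle over the whole series)
  r <- rle(pos)
  run_ends <- cumsum(r$lengths)
  run_starts <- run_ends - r$lengths + 1L
  starts <- run_starts[findInterval(ends, run_starts)]
  ev <- numeric(0)
  for (i in seq_along(ends)) {
    j <- ends[i]
    if (min(vz[starts[i]:j]) > -cfg$strike_min_downswing) next
    t_ev <- if (vz[j] < 0) {
      times[j] + (-vz[j]) / (vz[j + 1L] - vz[j]) * (times[j + 1L] - times[j])
    } else times[j]
    ev <- c(ev, t_ev)
  }
  if (!is.null(standing) && length(standing$t_start) > 0 && length(ev) > 0) {
    keep <- rep(TRUE, length(ev))
    for (r2 in seq_along(standing$t_start)) {
      keep <- keep & !(ev >= standing$t_start[r2] & ev <= standing$t_end[r2])
    }
    ev <- ev[keep]
  }
  if (length(ev) > 1L) {
    kept <- ev[1]
    for (t_ev in ev[-1]) {
      if (t_ev - kept[length(kept)] >= cfg$strike_refractory) kept <- c(kept, t_ev)
    }
    ev <- kept
  }
  ev
}

#' Detect standing periods
#'
#' Maximal intervals during which the horizontal speed of the body reference
#' point stays below `standing_speed_threshold` for at least
#' `standing_min_duration`.
#'
#' @param times sample times, s.
#' @param xy n x 2 matrix of horizontal body-reference positions (filtered).
#' @param cfg an [analysis_config()].
#' @param speed optional precomputed horizontal speed, m/s.
#' @return data frame with columns `t_start`, `t_end`.
#' @export
detect_standing <- function(times, xy = NULL, cfg = analysis_config(),
                            speed = NULL) {
  as.data.frame(standing_impl(times, xy, cfg, speed))
}

standing_impl <- function(times, xy = NULL, cfg, speed = NULL) {
  if (is.null(speed)) {
    v <- velocity(times, xy[, 1:2, drop = FALSE])
    speed <- sqrt(v[, 1]^2 + v[, 2]^2)
  }
  slow <- speed < cfg$standing_speed_threshold
  r <- rle(slow)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (times[ends] - times[starts] >= cfg$standing_min_duration)
  list(t_start = times[starts[keep]], t_end = times[ends[keep]])
}

#' Split a trial into orientation and navigation phases
#'
#' The orientation phase runs from eye opening (t = 0) to the first step
#' event; the navigation phase runs from the first step to trial end.
#'
#' @param events data frame of step events (`time`, `foot`).
#' @param trial_end trial end time, s.
#' @return list with elements `orientation = c(t0, t_first_step)` and
#'   `navigation = c(t_first_step, trial_end)`.
#' @export
split_phases <- function(events, trial_end) {
  if (is.null(events) || length(events$time) == 0L) {
    stop_nav("no step events: trial has no navigation phase")
  }
  t1 <- min(events$time)
  list(orientation = c(0, t1), navigation = c(t1, trial_end))
}

#' Heading of the body reference point
#'
#' Heading is the direction (degrees, unwrapped, 0 = +x, 90 = +y) of the
#' horizontal velocity of the centroid of the four eye-tracker-frame markers.
#' It is undefined (NA) wherever the horizontal speed falls below the
#' standing threshold.
#'
#' @param x a `marker_series` containing the eye-frame markers, or an
#'   n x 2/n x 3 position matrix.
#' @param cfg an [analysis_config()].
#' @param times sample times when `x` is a matrix.
#' @return data frame with columns `time`, `heading` (deg), `speed` (m/s).
#' @export
heading_series <- function(x, cfg = analysis_config(), times = NULL) {
  if (inherits(x, "marker_series")) {
    times <- x$times
    xy <- eye_frame_centroid(x)[, 1:2, drop = FALSE]
  } else {
    if (is.null(times)) stop_nav("times required with a position matrix")
    xy <- as.matrix(x)[, 1:2, drop = FALSE]
  }
  v <- velocity(times, xy)
  speed <- sqrt(v[, 1]^2 + v[, 2]^2)
  heading <- atan2(v[, 2], v[, 1]) * 180 / pi
  heading[speed < cfg$standing_speed_threshold] <- NA_real_
  heading <- unwrap_deg(heading)
  data.frame(time = times, heading = heading, speed = speed)
}

# 3-sample median smoothing that tolerates NA (median of available neighbors)
median3 <- function(x) {
  n <- length(x)
  if (n < 3L) return(x)
  a <- c(NA_real_, x[-n]); b <- x; cc <- c(x[-1], NA_real_)
  cnt <- (!is.na(a)) + (!is.na(b)) + (!is.na(cc))
  s <- rowSums(cbind(a, b, cc), na.rm = TRUE)
  mx <- pmax(a, b, cc, na.rm = TRUE)
  mn <- pmin(a, b, cc, na.rm = TRUE)
  out <- ifelse(cnt == 3L, s - mx - mn,      # true median of three
                ifelse(cnt == 2L, s / 2,     # median of two = mean
                       ifelse(cnt == 1L, s, NA_real_)))
  out[is.na(x)] <- NA_real_  # keep masked samples masked
  out
}

#' Segment steps between heel strikes and classify straight-ahead walking
#'
#' A step spans two consecutive heel strikes of opposite feet (same-foot
#' double strikes break the sequence). Heading at the step boundaries is read
#' from the heading series after 3-sample median smoothing; a step is
#' straight-ahead when the absolute wrapped heading change is strictly below
#' the straightness threshold. Step speed is the horizontal displacement of
#' the body reference point between the two strikes divided by step duration.
#'
#' @param events data frame of step events (`time`, `foot`), time-ordered.
#' @param heading a heading series from [heading_series()].
#' @param body_xy n x 2 matrix of body-reference positions on `body_times`.
#' @param body_times sample times for `body_xy`, s.
#' @param cfg an [analysis_config()].
#' @return data frame with one row per step: `t_start`, `t_end`,
#'   `foot_start`, `foot_end`, `heading_start`, `heading_end`,
#'   `heading_change`, `straight`, `speed`.
#' @export
segment_and_classify_steps <- function(events, heading, body_xy, body_times,
                                       cfg = analysis_config()) {
  ev_t <- events$time
  ev_f <- events$foot
  if (length(ev_t) < 2L) {
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      foot_start = character(0), foot_end = character(0),
                      heading_start = numeric(0), heading_end = numeric(0),
                      heading_change = numeric(0), straight = logical(0),
                      speed = numeric(0)))
  }
  o <- order(ev_t)
  ev_t <- ev_t[o]; ev_f <- ev_f[o]
  sm <- median3(heading$heading)
  ok <- !is.na(sm)
  h_ev <- if (sum(ok) < 2L) rep(NA_real_, length(ev_t)) else
    stats::approx(heading$time[ok], sm[ok], xout = ev_t, rule = 2)$y
  x_at <- stats::approx(body_times, body_xy[, 1], xout = ev_t, rule = 2)$y
  y_at <- stats::approx(body_times, body_xy[, 2], xout = ev_t, rule = 2)$y
  k <- length(ev_t) - 1L
  i <- seq_len(k)
  keep <- ev_f[i] != ev_f[i + 1L]
  dt <- ev_t[i + 1L] - ev_t[i]
  disp <- sqrt((x_at[i + 1L] - x_at[i])^2 + (y_at[i + 1L] - y_at[i])^2)
  dh <- wrap_angle(h_ev[i + 1L] - h_ev[i])
  straight <- !is.na(dh) & abs(dh) < cfg$straight_threshold
  data.frame(t_start = ev_t[i], t_end = ev_t[i + 1L],
             foot_start = ev_f[i], foot_end = ev_f[i + 1L],
             heading_start = h_ev[i], heading_end = h_ev[i + 1L],
             heading_change = dh, straight = straight,
             speed = disp / dt)[keep, , drop = FALSE]
}

#' Per-trial walking speed
#'
#' Median step speed over straight-ahead steps, after discarding the first
#' and last steps the participant performed (gait initiation/termination).
#'
#' @param steps step table from [segment_and_classify_steps()], in trial
#'   order.
#' @param cfg an [analysis_config()].
#' @return walking speed in m/s with attribute `n_eligible` (number of
#'   straight steps that entered the median). `NA` with a warning of class
#'   `navpace_insufficient_steps` when no eligible step remains.
#' @export
trial_walking_speed <- function(steps, cfg = analysis_config()) {
  n <- nrow(steps)
  eligible <- if (n > 2L) steps[-c(1L, n), , drop = FALSE] else steps[0, ]
  eligible <- eligible[eligible$straight, , drop = FALSE]
  if (nrow(eligible) < 1L) {
    warning(warningCondition("insufficient steps for walking speed",
                             class = "navpace_insufficient_steps"))
    return(structure(NA_real_, n_eligible = 0L))
  }
  structure(stats::median(eligible$speed), n_eligible = nrow(eligible))
}

#' Fraction of the navigation phase spent in straight-ahead walking
#'
#' @param steps step table.
#' @param phases phase list from [split_phases()].
#' @return proportion in \[0, 1\].
#' @export
straight_fraction <- function(steps, phases) {
  nav <- phases$navigation
  dur <- nav[2] - nav[1]
  if (dur <= 0) stop_nav("empty navigation phase")
  if (nrow(steps) == 0L) return(0)
  a <- pmax(steps$t_start, nav[1])
  b <- pmin(steps$t_end, nav[2])
  covered <- sum(pmax(b - a, 0)[steps$straight])
  min(covered / dur, 1)
}

#' First crossing of the goal-zone border
#'
#' @param times sample times, s.
#' @param xy n x 2 horizontal body-reference positions.
#' @param env a `nav_environment`.
#' @return crossing time (s), linearly interpolated, or `NA` if the
#'   trajectory never enters the goal zone.
#' @export
detect_goal_crossing <- function(times, xy, env) {
  half <- env$goal_zone$side / 2
  ctr <- env$goal_zone$center
  cheb <- pmax(abs(xy[, 1] - ctr[1]), abs(xy[, 2] - ctr[2]))
  inside <- cheb <= half
  if (!any(inside)) return(NA_real_)
  j <- which(inside)[1]
  if (j == 1L) return(times[1])
  # interpolate where the Chebyshev distance reaches the border
  f <- (cheb[j - 1L] - half) / (cheb[j - 1L] - cheb[j])
  times[j - 1L] + f * (times[j] - times[j - 1L])
}
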