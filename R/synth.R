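# Synthetic-cohort generator. Emulates the study conditions end to end:
# two age groups walking from one of four start poses to an invisible goal
# zone in the instrumented room, with per-trial programmed walking speed,
# path directness (true trajectory efficiency) and goal-fixation
# probability, a rectified-sinusoid heel swing phase-locked to programmed
# heel-strike times, and a fixation-saccade gaze process over the room
# surfaces. Every trial is returned together with its ground truth so the
# detectors can be scored.

#' Navigator parameters for one participant
#'
#' @param speeds per-trial target (cruise) walking speed, m/s.
#' @param directness per-trial path directness in (0, 1]; programs the true
#'   trajectory efficiency of the trial.
#' @param goal_fix_prob per-trial probability that a fixation targets the
#'   goal area.
#' @param step_frequency steps per second (both feet), Hz.
#' @param step_length optional step length, m; when given, it overrides
#'   `step_frequency` via `frequency = speed / step_length`.
#' @param step_height peak heel lift during swing, m.
#' @param eye_height height of the eye-frame centroid, m.
#' @param fixation_median,fixation_sigma median (s) and log-sd of the
#'   log-normal fixation-duration distribution.
#' @param saccade_min_separation minimum distance between successive fixation
#'   targets on the room surfaces, m.
#' @param noise_pos additive i.i.d. Gaussian noise on marker positions, m.
#' @param noise_dir angular noise on gaze directions, radians.
#' @param orientation_duration nominal orientation-phase duration, s.
#' @param start_positions k x 2 matrix of candidate start positions, m.
#' @param start_offset integer offset into the start-position cycle.
#' @return an object of class `navigator_params`.
#' @export
navigator_params <- function(speeds, directness, goal_fix_prob,
                             step_frequency = 1.8, step_length = NULL,
                             step_height = 0.05, eye_height = 1.62,
                             fixation_median = 0.30, fixation_sigma = 0.4,
                             saccade_min_separation = 0.5,
                             noise_pos = 0.001, noise_dir = 0.003,
                             orientation_duration = 1.5,
                             start_positions = default_start_positions(),
                             start_offset = 0L) {
  n <- length(speeds)
  if (length(directness) != n || length(goal_fix_prob) != n) {
    stop_nav("speeds, directness and goal_fix_prob must have equal length")
  }
  if (any(speeds <= 0)) stop_nav("speeds must be > 0")
  if (any(directness <= 0 | directness > 1)) {
    stop_nav("directness must lie in (0, 1]")
  }
  if (any(goal_fix_prob < 0 | goal_fix_prob > 1)) {
    stop_nav("goal_fix_prob must lie in [0, 1]")
  }
  stopifnot(step_frequency > 0, step_height > 0, noise_pos >= 0, noise_dir >= 0,
            orientation_duration > 0.8)
  structure(list(speeds = speeds, directness = directness,
                 goal_fix_prob = goal_fix_prob,
                 step_frequency = step_frequency, step_length = step_length,
                 step_height = step_height, eye_height = eye_height,
                 fixation_median = fixation_median,
                 fixation_sigma = fixation_sigma,
                 saccade_min_separation = saccade_min_separation,
                 noise_pos = noise_pos, noise_dir = noise_dir,
                 orientation_duration = orientation_duration,
                 start_positions = as.matrix(start_positions),
                 start_offset = as.integer(start_offset)),
            class = "navigator_params")
}

#' Default start positions (four poses away from the goal quadrant)
#' @return 4 x 2 matrix, meters.
#' @export
default_start_positions <- function() {
  rbind(c(6.5, 1.1), c(7.5, 3.2), c(4.3, 0.9), c(5.3, 3.4))
}

# ---------------------------------------------------------------------------
# Path construction: a smooth sinusoidal-deviation curve from the start to
# the goal border whose arc length, truncated at the first border crossing,
# equals dist(start, goal center) / directness -- so the analysis-side
# trajectory efficiency equals the programmed directness by construction.

build_path <- function(start, center, directness, env, margin = 0.12,
                       n_grid = 351L) {
  D <- sqrt(sum((center - start)^2))
  if (D <= env$goal_zone$side) stop_nav("start position lies (almost) inside the goal zone")
  L_target <- D / directness
  u <- (center - start) / D
  nv <- c(-u[2], u[1])
  sg <- seq(0, 1, length.out = n_grid)
  half <- env$goal_zone$side / 2
  base_x <- start[1] + sg * (center[1] - start[1])
  base_y <- start[2] + sg * (center[2] - start[2])

  # polyline truncated at the first goal-border crossing, for one amplitude
  shape <- function(A, sink, sgn) {
    off <- sgn * A * sink
    x <- base_x + off * nv[1]
    y <- base_y + off * nv[2]
    cheb <- pmax.int(abs(x - center[1]), abs(y - center[2]))
    j <- match(TRUE, cheb <= half)
    if (is.na(j) || j == 1L) return(NULL)
    f <- (cheb[j - 1L] - half) / (cheb[j - 1L] - cheb[j])
    xj <- x[j - 1L] + f * (x[j] - x[j - 1L])
    yj <- y[j - 1L] + f * (y[j] - y[j - 1L])
    x <- c(x[seq_len(j - 1L)], xj)
    y <- c(y[seq_len(j - 1L)], yj)
    dx <- x[-1L] - x[-j]
    dy <- y[-1L] - y[-j]
    list(x = x, y = y, seg = sqrt(dx * dx + dy * dy))
  }

  # one-sided smooth bulges (sin^2) so the amplitude search can always keep
  # the detour away from the nearest wall; k controls the number of bulges
  for (k in 1:6) for (sgn in c(1, -1)) {
    sink <- sin(pi * k * sg)^2
    f <- function(A) {
      p <- shape(A, sink, sgn)
      if (is.null(p)) NA_real_ else sum(p$seg) - L_target
    }
    f_lo <- f(0)
    if (is.na(f_lo)) next
    hi <- 0.2; f_hi <- f(hi); tries <- 0L
    while (!is.na(f_hi) && f_hi < 0 && tries < 8L) {
      hi <- hi * 1.8; f_hi <- f(hi); tries <- tries + 1L
    }
    if (is.na(f_hi) || f_hi < 0) next
    A <- if (f_lo >= 0) 0 else stats::uniroot(f, c(0, hi), tol = 1e-3)$root
    p <- shape(A, sink, sgn)
    if (!all(p$x >= margin & p$x <= env$room_length - margin &
               p$y >= margin & p$y <= env$room_width - margin)) next
    cum <- c(0, cumsum(p$seg))
    ang <- unwrap_deg(atan2(diff(p$y), diff(p$x)) * 180 / pi)
    return(list(points = cbind(p$x, p$y), cumlen = cum,
                length = cum[length(cum)],
                tangent = c(ang, ang[length(ang)])))
  }
  stop_nav("programmed directness ", signif(directness, 3),
           " is incompatible with the room geometry from this start position")
}

# ---------------------------------------------------------------------------
# Fixation-target samplers over the environment surfaces.

surface_is_floor <- function(s) abs(s$normal[3]) > 0.99

sample_panel_point <- function(s) {
  v <- s$vertices
  h <- max(v[, 3]) - min(v[, 3])
  wlo <- min(0.85, 0.4 / max(h, 0.5))
  whi <- max(wlo + 0.05, min(0.85, 2.5 / max(h, 0.5)))
  u <- stats::runif(1, 0.1, 0.9)
  w <- stats::runif(1, wlo, whi)
  v[1, ] + u * (v[2, ] - v[1, ]) + w * (v[4, ] - v[1, ])
}

# Point jitter on a surface grows with ray length and grazing incidence
# (amplification = range / cos(incidence)); people fixate points they can
# resolve, so candidate targets with amplification beyond amp_max are
# resampled. eye_h is the assumed eye height for floor geometry.
target_amplification <- function(point, normal, origin3) {
  dvec <- point - origin3
  rng <- sqrt(sum(dvec^2))
  cosi <- abs(sum(dvec * normal)) / max(rng, 1e-9)
  rng / max(cosi, 0.1)
}

sample_fixation_target <- function(env, in_goal, origin = NULL,
                                   eye_h = 1.62, amp_max = 6.5) {
  panels <- Filter(Negate(surface_is_floor), env$surfaces)
  goal_ids <- env$goal_area_surface_ids
  gp <- env$goal_floor_polygon
  origin3 <- if (is.null(origin)) NULL else c(origin[1:2], eye_h)
  pick_panel <- function(cands) {
    best <- NULL; best_amp <- Inf
    for (i in 1:8) {
      s <- cands[[sample.int(length(cands), 1)]]
      pt <- sample_panel_point(s)
      if (is.null(origin3)) return(list(point = pt, surface = s$id))
      amp <- target_amplification(pt, s$normal, origin3)
      if (amp <= amp_max) return(list(point = pt, surface = s$id))
      if (amp < best_amp) { best <- list(point = pt, surface = s$id); best_amp <- amp }
    }
    best
  }
  if (in_goal) {
    goal_panels <- Filter(function(s) s$id %in% goal_ids, panels)
    gctr <- colMeans(gp)
    near_goal <- is.null(origin3) ||
      sqrt(sum((origin3[1:2] - gctr)^2)) <= 3.2
    use_floor <- "floor" %in% goal_ids && near_goal &&
      (length(goal_panels) == 0L || stats::runif(1) < 0.35)
    if (use_floor) {
      for (i in 1:25) {
        p <- c(stats::runif(1, min(gp[, 1]), max(gp[, 1])),
               stats::runif(1, min(gp[, 2]), max(gp[, 2])))
        if (points_in_polygon(p[1], p[2], gp)) {
          return(list(point = c(p, 0), surface = "floor"))
        }
      }
    }
    return(pick_panel(goal_panels))
  }
  if (!is.null(origin3) && stats::runif(1) < 0.25) {
    # floor fixation near the walker, away from the goal area
    avoid <- inflate_rect(gp, 0.15)
    for (i in 1:25) {
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- stats::runif(1, 0.8, 2.6)
      p <- origin3[1:2] + rad * c(cos(ang), sin(ang))
      if (p[1] > 0.3 && p[1] < env$room_length - 0.3 &&
            p[2] > 0.3 && p[2] < env$room_width - 0.3 &&
            !points_in_polygon(p[1], p[2], avoid)) {
        return(list(point = c(p, 0), surface = "floor"))
      }
    }
  }
  pick_panel(Filter(function(s) !s$id %in% goal_ids, panels))
}

inflate_rect <- function(poly, by) {
  ctr <- colMeans(poly)
  t(apply(poly, 1, function(v) v + sign(v - ctr) * by))
}

# ---------------------------------------------------------------------------

#' Generate one synthetic trial
#'
#' Produces a `trial_recording` (markers at 120 Hz, gaze at 60 Hz) and its
#' ground truth. The walked curve runs from the trial's start pose to the
#' goal-zone border with a truncated arc length of
#' `dist(start, goal center) / directness`, so the trial's true trajectory
#' efficiency equals the programmed directness. Heel markers follow a
#' rectified-sinusoid swing whose downward-to-upward vertical-velocity
#' crossings occur exactly at the programmed strike times. Gaze alternates
#' fixations (stationary target on a surface, tracked while walking) with
#' instantaneous saccades; each fixation targets the goal area with the
#' programmed probability.
#'
#' @param env a `nav_environment`.
#' @param params a `navigator_params`.
#' @param trial_index which per-trial parameter set to use (1-based).
#' @param seed optional integer; the same `env`, `params`, `trial_index` and
#'   `seed` reproduce the recording bit-identically.
#' @param include_gaze generate the gaze stream (disable for kinematics-only
#'   studies).
#' @param participant_id,group metadata carried into the recording.
#' @return list with elements `recording` (a `trial_recording`) and `truth`
#'   (list: `strikes` data frame, `first_step`, `t_cross`, `speed`,
#'   `efficiency`, `goal_fix_prob`, `fixations` data frame,
#'   `goal_fix_proportion`).
#' @export
generate_trial <- function(env, params, trial_index = 1L, seed = NULL,
                           include_gaze = TRUE, participant_id = "synthetic",
                           group = "young") {
  stopifnot(inherits(env, "nav_environment"),
            inherits(params, "navigator_params"))
  if (trial_index > length(params$speeds)) {
    stop_nav("trial_index exceeds the programmed number of trials")
  }
  with_seed(seed, {
    rate <- 120
    v <- params$speeds[trial_index]
    dct <- params$directness[trial_index]
    pg <- params$goal_fix_prob[trial_index]
    sp <- params$start_positions
    start <- sp[((trial_index - 1L + params$start_offset) %% nrow(sp)) + 1L, ]
    path <- build_path(start, env$goal_zone$center, dct, env)

    t_orient <- params$orientation_duration * stats::runif(1, 0.9, 1.1)
    tr <- 0.6                               # speed ramp-up duration
    t_cross <- tr / 2 + path$length / v     # time to reach the border
    t_total <- t_orient + t_cross + 0.3
    times <- seq(0, t_total, by = 1 / rate)
    n <- length(times)

    tw <- times - t_orient
    s_of <- v * (tw - tr / 2)
    ramp <- tw < tr
    s_of[ramp] <- v / 2 * (tw[ramp] - tr / pi * sin(pi * tw[ramp] / tr))
    s_of[tw <= 0] <- 0
    s_of <- pmin(s_of, path$length)
    x <- stats::approx(path$cumlen, path$points[, 1], xout = s_of)$y
    y <- stats::approx(path$cumlen, path$points[, 2], xout = s_of)$y
    hdg <- stats::approx(path$cumlen, path$tangent, xout = s_of)$y

    # programmed heel strikes: alternating feet, one per half gait cycle
    f_step <- if (!is.null(params$step_length)) v / params$step_length else
      params$step_frequency
    h_step <- 1 / f_step
    t_first <- t_orient + 0.45
    t_cross_abs <- t_orient + t_cross
    strike_times <- seq(t_first, t_cross_abs - 0.02, by = h_step)
    if (length(strike_times) < 2L) {
      stop_nav("trial too short to contain two steps; check speeds/geometry")
    }
    first_foot <- sample(c("left", "right"), 1)
    feet <- rep(c(first_foot, setdiff(c("left", "right"), first_foot)),
                length.out = length(strike_times))

    heel_z <- function(tk) {
      # rectified-sinusoid swing: zero height and a downward-to-upward
      # velocity sign change exactly at each strike
      knots <- c(tk[1] - 0.45, tk)
      j <- findInterval(times, knots)
      z <- numeric(n)
      inside <- j >= 1L & j < length(knots)
      jj <- j[inside]
      phase <- (times[inside] - knots[jj]) / (knots[jj + 1L] - knots[jj])
      z[inside] <- params$step_height * sin(pi * phase)^2
      z
    }
    tk_l <- strike_times[feet == "left"]
    tk_r <- strike_times[feet == "right"]
    perp <- cbind(-sin(hdg * pi / 180), cos(hdg * pi / 180))
    noise <- function(nr, nc = 3) matrix(stats::rnorm(nr * nc, 0, params$noise_pos),
                                         nr, nc)
    heel_l <- cbind(x + 0.09 * perp[, 1], y + 0.09 * perp[, 2], 0.03 + heel_z(tk_l))
    heel_r <- cbind(x - 0.09 * perp[, 1], y - 0.09 * perp[, 2], 0.03 + heel_z(tk_r))

    ch <- cos(hdg * pi / 180); sh <- sin(hdg * pi / 180)
    offs <- 0.07 * rbind(c(1, 1), c(1, -1), c(-1, -1), c(-1, 1))
    zoff <- c(0.02, -0.02, 0.02, -0.02)
    eye <- lapply(1:4, function(i) {
      ox <- offs[i, 1] * ch - offs[i, 2] * sh
      oy <- offs[i, 1] * sh + offs[i, 2] * ch
      cbind(x + ox, y + oy, params$eye_height + zoff[i]) + noise(n)
    })
    positions <- list(heel_l + noise(n), heel_r + noise(n),
                      eye[[1]], eye[[2]], eye[[3]], eye[[4]])
    names(positions) <- c(HEEL_LEFT, HEEL_RIGHT, EYE_FRAME)
    markers <- marker_series(times, positions, rate = rate, validate = FALSE)

    truth <- list(
      strikes = data.frame(time = strike_times, foot = feet),
      first_step = t_first, t_cross = t_cross_abs,
      speed = v, efficiency = dct, goal_fix_prob = pg,
      path = path$points,
      fixations = NULL, goal_fix_proportion = NA_real_)

    gaze <- NULL
    if (include_gaze) {
      g <- generate_gaze(env, params, times, x, y, pg, t_total)
      gaze <- g$gaze
      truth$fixations <- g$fixations
      truth$goal_fix_proportion <- g$goal_fix_proportion
    }
    rec <- trial_recording(participant_id, group, trial_index, start,
                           markers, gaze, trial_end_time = t_cross_abs)
    list(recording = rec, truth = truth)
  })
}

generate_gaze <- function(env, params, times, x, y, pg, t_total) {
  grate <- 60
  t60 <- seq(0, t_total, by = 1 / grate)
  m <- length(t60)
  # fixation schedule
  durs <- numeric(0)
  while (sum(durs) < t_total) {
    d <- stats::rlnorm(16, log(params$fixation_median), params$fixation_sigma)
    durs <- c(durs, pmin(pmax(d, 0.1), 1.5))
  }
  nf <- which(cumsum(durs) >= t_total)[1]
  durs <- durs[seq_len(nf)]
  bounds <- c(0, cumsum(durs))
  bounds[nf + 1L] <- t_total + 1e-6
  in_goal <- stats::runif(nf) < pg
  targets <- matrix(NA_real_, nf, 3)
  surfaces <- character(nf)
  prev <- c(Inf, Inf, Inf)
  bx <- stats::approx(times, x, xout = pmin(bounds[seq_len(nf)], t_total),
                      rule = 2)$y
  by <- stats::approx(times, y, xout = pmin(bounds[seq_len(nf)], t_total),
                      rule = 2)$y
  for (j in seq_len(nf)) {
    for (try in 1:8) {
      tg <- sample_fixation_target(env, in_goal[j], origin = c(bx[j], by[j]))
      if (sqrt(sum((tg$point - prev)^2)) >= params$saccade_min_separation) break
    }
    targets[j, ] <- tg$point
    surfaces[j] <- tg$surface
    prev <- tg$point
  }
  fi <- findInterval(t60, bounds, rightmost.closed = TRUE)
  fi[fi < 1L] <- 1L; fi[fi > nf] <- nf
  ex <- stats::approx(times, x, xout = t60, rule = 2)$y
  ey <- stats::approx(times, y, xout = t60, rule = 2)$y
  org <- cbind(ex, ey, params$eye_height) +
    matrix(stats::rnorm(3 * m, 0, params$noise_pos), m, 3)
  dvec <- targets[fi, , drop = FALSE] - org
  dvec <- dvec / row_norms(dvec)
  # angular noise in the plane orthogonal to the line of sight
  e1 <- cbind(-dvec[, 2], dvec[, 1], 0)
  n1 <- row_norms(e1)
  vertical <- n1 < 1e-6
  if (any(vertical)) {
    e1[vertical, ] <- matrix(c(1, 0, 0), sum(vertical), 3, byrow = TRUE)
  }
  e1 <- e1 / row_norms(e1)
  e2 <- cbind(dvec[, 2] * e1[, 3] - dvec[, 3] * e1[, 2],
              dvec[, 3] * e1[, 1] - dvec[, 1] * e1[, 3],
              dvec[, 1] * e1[, 2] - dvec[, 2] * e1[, 1])
  z1 <- stats::rnorm(m, 0, params$noise_dir)
  z2 <- stats::rnorm(m, 0, params$noise_dir)
  dvec <- dvec + z1 * e1 + z2 * e2
  dvec <- dvec / row_norms(dvec)
  gaze <- gaze_series(t60, org, dvec, rate = grate, validate = FALSE)
  # realized fixation boundaries: first/last gaze sample on each target
  first_idx <- match(seq_len(nf), fi)
  last_idx <- m + 1L - match(seq_len(nf), rev(fi))
  present <- !is.na(first_idx)
  fixations <- data.frame(t_start = t60[first_idx[present]],
                          t_end = t60[last_idx[present]],
                          surface_id = surfaces[present],
                          in_goal = in_goal[present])
  list(gaze = gaze, fixations = fixations,
       goal_fix_proportion = mean(in_goal[present]))
}
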