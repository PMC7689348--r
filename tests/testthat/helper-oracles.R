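# Shared fixtures and independent brute-force oracles. Oracles are written
# as straightforward loops, independent of the vectorized implementation
# paths they check.

nav_env <- environment_model()

# --- heel-strike oracle: enumerate every sign change of the discrete
# vertical velocity and apply the cleaning rules one event at a time.
oracle_heel_strikes <- function(times, vz, cfg, standing = NULL) {
  ev <- numeric(0)
  run_min <- Inf
  n <- length(vz)
  for (i in seq_len(n)) {
    if (vz[i] <= 0) {
      run_min <- min(run_min, vz[i])
      if (i < n && vz[i + 1] > 0) {
        if (run_min <= -cfg$strike_min_downswing) {
          t_ev <- if (vz[i] < 0) {
            times[i] + (-vz[i]) / (vz[i + 1] - vz[i]) * (times[i + 1] - times[i])
          } else times[i]
          ev <- c(ev, t_ev)
        }
        run_min <- Inf
      }
    } else {
      run_min <- Inf
    }
  }
  if (!is.null(standing) && length(standing$t_start) > 0) {
    for (r in seq_along(standing$t_start)) {
      ev <- ev[!(ev >= standing$t_start[r] & ev <= standing$t_end[r])]
    }
  }
  out <- numeric(0)
  for (t_ev in ev) {
    if (length(out) == 0L || t_ev - out[length(out)] >= cfg$strike_refractory) {
      out <- c(out, t_ev)
    }
  }
  out
}

# --- fixation oracle: recompute dispersions pairwise, then walk the trace
# start-by-start enumerating every maximal below-threshold run.
oracle_fixations <- function(points, cfg) {
  n <- length(points$times)
  d <- rep(NA_real_, n - 1L)
  for (i in seq_len(n - 1L)) {
    if (points$valid[i] && points$valid[i + 1L]) {
      d[i] <- sqrt(sum((points$points[i + 1L, ] - points$points[i, ])^2))
    }
  }
  dv <- d[!is.na(d)]
  thr <- stats::median(dv) + cfg$dispersion_k * stats::IQR(dv)
  below <- !is.na(d) & (d < thr | d <= stats::median(dv))
  fixs <- list()
  i <- 1L
  while (i <= length(below)) {
    if (below[i]) {
      j <- i
      while (j < length(below) && below[j + 1L]) j <- j + 1L
      t0 <- points$times[i]; t1 <- points$times[j + 1L]
      if ((t1 - t0) * 1000 >= cfg$min_fixation) {
        idx <- i:(j + 1L)
        ctr <- colMeans(points$points[idx, , drop = FALSE])
        tab <- table(points$surface_id[idx])
        fixs[[length(fixs) + 1L]] <- data.frame(
          t_start = t0, t_end = t1, duration_ms = (t1 - t0) * 1000,
          x = ctr[1], y = ctr[2], z = ctr[3],
          surface_id = names(tab)[which.max(tab)], in_goal_area = NA)
      }
      i <- j + 2L
    } else {
      i <- i + 1L
    }
  }
  if (length(fixs) == 0L) {
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      duration_ms = numeric(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), surface_id = character(0),
                      in_goal_area = logical(0)))
  }
  out <- do.call(rbind, fixs)
  rownames(out) <- NULL
  out
}

# --- ray-surface oracle: test every surface independently; point-in-polygon
# by winding angle rather than ray crossings.
oracle_intersect_one <- function(origin, direction, env) {
  best_t <- Inf; best <- NULL
  for (s in env$surfaces) {
    denom <- sum(direction * s$normal)
    if (abs(denom) < 1e-12) next
    tt <- sum((s$origin - origin) * s$normal) / denom
    if (tt <= 1e-9 || tt >= best_t) next
    p <- origin + tt * direction
    u <- p[s$proj_axes[1]]; v <- p[s$proj_axes[2]]
    poly <- s$poly2d
    ang <- 0
    k <- nrow(poly)
    for (i in seq_len(k)) {
      a <- c(poly[i, 1] - u, poly[i, 2] - v)
      b <- c(poly[i %% k + 1, 1] - u, poly[i %% k + 1, 2] - v)
      ang <- ang + atan2(a[1] * b[2] - a[2] * b[1], sum(a * b))
    }
    if (abs(ang) > pi) {    # winding number nonzero -> inside
      best_t <- tt
      best <- list(point = p, surface = s$id, t = tt)
    }
  }
  best
}

# --- criterion-trial oracle: brute-force scan over trial pairs.
oracle_criterion <- function(te, criterion) {
  for (i in seq_len(length(te) - 1L)) {
    if (!is.na(te[i]) && !is.na(te[i + 1]) &&
          te[i] > criterion && te[i + 1] > criterion) {
      return(i)
    }
  }
  length(te)
}

# --- polyline arc length, summed in a plain loop.
oracle_arclength <- function(path) {
  len <- 0
  for (i in seq_len(nrow(path) - 1L)) {
    len <- len + sqrt(sum((path[i + 1L, ] - path[i, ])^2))
  }
  len
}

# construct a gaze_points object directly (bypassing ray casting)
make_gaze_points <- function(times, points, surface_id = NULL, valid = NULL) {
  n <- length(times)
  structure(list(times = times, points = points,
                 surface_id = surface_id %||% rep("panel_n1", n),
                 valid = valid %||% rep(TRUE, n)),
            class = "gaze_points")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a random gaze-point trace with fixation clusters, saccade jumps and
# occasional invalid patches (for oracle-equivalence tests)
random_gaze_trace <- function(n, rate = 120) {
  times <- seq(0, by = 1 / rate, length.out = n)
  pts <- matrix(0, n, 3)
  surf <- character(n)
  centers <- cbind(runif(40, 0, 8), runif(40, 0, 4.3), runif(40, 0.3, 2.5))
  i <- 1L; k <- 1L
  while (i <= n) {
    len <- sample(3:60, 1)
    idx <- i:min(n, i + len - 1L)
    ctr <- centers[(k - 1L) %% 40 + 1L, ]
    pts[idx, ] <- matrix(ctr, length(idx), 3, byrow = TRUE) +
      matrix(rnorm(3 * length(idx), 0, 0.012), length(idx), 3)
    surf[idx] <- paste0("panel_n", (k %% 5) + 1L)
    i <- i + len; k <- k + 1L
  }
  valid <- runif(n) > 0.03
  make_gaze_points(times, pts, surf, valid)
}

# random vertical-velocity trace mixing gait-like oscillation, drift and
# flat standing stretches (for heel-strike oracle tests)
random_vz_trace <- function(n, rate = 120) {
  times <- seq(0, by = 1 / rate, length.out = n)
  f <- runif(1, 0.6, 1.4)
  vz <- 0.15 * sin(2 * pi * f * times + runif(1, 0, 2 * pi)) +
    rnorm(n, 0, 0.03)
  if (runif(1) < 0.5) {
    i0 <- sample(seq_len(max(n - 60, 1)), 1)
    vz[i0:min(n, i0 + 59)] <- rnorm(min(60, n - i0 + 1), 0, 0.002)
  }
  list(times = times, vz = vz)
}
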