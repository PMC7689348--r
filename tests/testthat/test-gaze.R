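cfgg <- analysis_config()

test_that("resampling interpolates origins linearly and directions on the sphere", {
  t60 <- seq(0, 1, by = 1 / 60)
  n <- length(t60)
  const <- gaze_series(t60, matrix(rep(c(1, 2, 1.6), each = n), n, 3),
                       matrix(rep(c(1, 0, 0), each = n), n, 3), rate = 60)
  rs <- resample_gaze(const, 120)
  expect_true(all(rs$valid))
  expect_true(all(abs(rs$directions[, 1] - 1) < 1e-12))
  # two samples 1/60 s apart -> inserted midpoint
  two <- gaze_series(c(0, 1 / 60), rbind(c(0, 0, 1.6), c(0.1, 0, 1.6)),
                     rbind(c(1, 0, 0), c(0, 1, 0)), rate = 60)
  rs2 <- resample_gaze(two, 120)
  expect_equal(rs2$origins[2, 1], 0.05, tolerance = 1e-9)
  expect_equal(rs2$directions[2, ], c(1, 1, 0) / sqrt(2), tolerance = 1e-9)
  # rotating direction stays unit-norm after slerp
  th <- 10 * pi / 180 * t60
  rot <- gaze_series(t60, matrix(0, n, 3), cbind(cos(th), sin(th), 0),
                     rate = 60)
  rs3 <- resample_gaze(rot, 120)
  expect_lt(max(abs(sqrt(rowSums(rs3$directions^2)) - 1)), 1e-9)
})

test_that("gaps longer than 200 ms are flagged invalid, not interpolated", {
  tt <- c(seq(0, 0.5, by = 1 / 60), seq(0.8, 1.3, by = 1 / 60))
  n <- length(tt)
  g <- gaze_series(tt, matrix(0, n, 3),
                   matrix(rep(c(1, 0, 0), each = n), n, 3), rate = 60)
  rs <- resample_gaze(g, 120)
  in_gap <- rs$times > 0.51 & rs$times < 0.79
  expect_true(all(!rs$valid[in_gap]))
  expect_true(all(rs$valid[rs$times < 0.5]))
})

test_that("ray casting finds the nearest forward surface hit", {
  # perpendicular ray at the north wall from 2 m away
  ctr <- c(3, nav_env$room_width - 2, 1.5)
  g <- gaze_series(0, matrix(ctr, 1, 3), matrix(c(0, 1, 0), 1, 3), rate = 60)
  gp <- intersect_gaze(g, nav_env)
  expect_true(gp$valid[1])
  expect_equal(gp$points[1, ], c(3, nav_env$room_width, 1.5), tolerance = 1e-9)
  expect_match(gp$surface_id[1], "panel_n")
  # upward ray escapes the open ceiling
  up <- gaze_series(0, matrix(ctr, 1, 3), matrix(c(0, 0, 1), 1, 3), rate = 60)
  expect_false(intersect_gaze(up, nav_env)$valid[1])
})

test_that("ray casting agrees with the all-surface brute-force oracle", {
  set.seed(55)
  n <- 300
  org <- cbind(runif(n, 0.5, 8), runif(n, 0.5, 3.8), runif(n, 1.0, 1.9))
  dirs <- matrix(rnorm(3 * n), n, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  g <- gaze_series(seq_len(n) / 120, org, dirs, rate = 120)
  gp <- intersect_gaze(g, nav_env)
  for (i in seq_len(n)) {
    want <- oracle_intersect_one(org[i, ], dirs[i, ], nav_env)
    if (is.null(want)) {
      expect_false(gp$valid[i])
    } else {
      expect_true(gp$valid[i])
      expect_equal(gp$surface_id[i], want$surface)
      expect_equal(gp$points[i, ], want$point, tolerance = 1e-9,
                   ignore_attr = TRUE)
    }
  }
})

test_that("valid intersection points lie on their named surface", {
  p <- navigator_params(speeds = 1.1, directness = 0.85, goal_fix_prob = 0.4)
  g <- generate_trial(nav_env, p, 1, seed = 70)
  rg <- resample_gaze(g$recording$gaze, 120)
  gp <- intersect_gaze(rg, nav_env)
  ok <- which(gp$valid)
  dist_to_plane <- vapply(ok, function(i) {
    s <- nav_env$surfaces[[gp$surface_id[i]]]
    abs(sum((gp$points[i, ] - s$origin) * s$normal))
  }, numeric(1))
  expect_lt(max(dist_to_plane), 1e-6)
})

test_that("dispersion is the distance between successive valid points", {
  t <- seq_len(6) / 120
  pts <- matrix(rep(c(1, 1, 1), each = 6), 6, 3)
  expect_equal(dispersion_series(make_gaze_points(t, pts)), rep(0, 5))
  stepped <- cbind(seq(0, by = 0.01, length.out = 6), rep(0, 6), rep(0, 6))
  expect_equal(dispersion_series(make_gaze_points(t, stepped)),
               rep(0.01, 5), tolerance = 1e-12)
  alt <- cbind(rep(c(0, 1), 3), rep(0, 6), rep(0, 6))
  expect_equal(dispersion_series(make_gaze_points(t, alt)), rep(1, 5))
  gpv <- make_gaze_points(t, stepped, valid = c(TRUE, TRUE, FALSE, TRUE,
                                                TRUE, TRUE))
  d <- dispersion_series(gpv)
  expect_true(is.na(d[2]) && is.na(d[3]) && !is.na(d[4]))
})

make_cluster_trace <- function(cluster_len, rate = 120, seed = 5) {
  # normal scanning gaze: short (sub-100 ms) stops separated by large
  # saccades, with one long stationary cluster in the middle
  set.seed(seed)
  short_stop <- function(k) {
    ctr <- c(runif(1, 0.5, 8), runif(1, 0.5, 4), runif(1, 0.5, 2.5))
    matrix(ctr, k, 3, byrow = TRUE) + matrix(rnorm(3 * k, 0, 0.004), k, 3)
  }
  pre <- do.call(rbind, lapply(rep(8, 6), short_stop))
  post <- do.call(rbind, lapply(rep(8, 6), short_stop))
  cluster <- matrix(c(4, 2, 1.5), cluster_len, 3, byrow = TRUE) +
    matrix(rnorm(3 * cluster_len, 0, 0.004), cluster_len, 3)
  pts <- rbind(pre, cluster, post)
  t <- seq_len(nrow(pts)) / rate
  attr(t, "cluster_idx") <- nrow(pre) + c(1L, cluster_len)
  out <- make_gaze_points(t, pts)
  out$cluster_span <- t[nrow(pre) + c(1L, cluster_len)]
  out
}

test_that("dispersion-threshold fixation detection honours the 100 ms rule", {
  tr30 <- make_cluster_trace(30)
  fx30 <- detect_fixations(tr30, cfgg)
  expect_equal(nrow(fx30), 1L)
  expect_equal(fx30$t_start, tr30$cluster_span[1], tolerance = 1.5 / 120)
  expect_equal(fx30$t_end, tr30$cluster_span[2], tolerance = 1.5 / 120)
  expect_equal(fx30, oracle_fixations(tr30, cfgg), ignore_attr = TRUE)
  tr10 <- make_cluster_trace(10)
  expect_equal(nrow(detect_fixations(tr10, cfgg)), 0L)
  # a whole stationary trace is one fixation spanning it
  n <- 120
  t <- seq_len(n) / 120
  still <- matrix(c(4, 2, 1.5), n, 3, byrow = TRUE)
  fx <- detect_fixations(make_gaze_points(t, still), cfgg)
  expect_equal(nrow(fx), 1L)
  expect_equal(fx$t_start, t[1])
  expect_equal(fx$t_end, t[n])
})

test_that("raising the dispersion multiplier never shrinks fixation time", {
  set.seed(77)
  for (k in 1:10) {
    tr <- random_gaze_trace(sample(300:900, 1))
    tot <- vapply(c(1, 2, 3, 5), function(kk) {
      fx <- detect_fixations(tr, analysis_config(dispersion_k = kk))
      sum(fx$t_end - fx$t_start)
    }, numeric(1))
    expect_true(all(diff(tot) >= -1e-12))
  }
})

test_that("goal-area classification combines surface set and floor polygon", {
  gfx <- data.frame(t_start = c(0, 0, 0, 0), t_end = c(1, 1, 1, 1),
                    duration_ms = 1000,
                    x = c(2.1, 8.0, 2.1, 6.0),
                    y = c(4.0, 1.0, 3.2, 1.0),
                    z = c(1.5, 1.5, 0, 0),
                    surface_id = c("panel_n2", "panel_e2", "floor", "floor"),
                    in_goal_area = NA)
  cls <- classify_goal_fixations(gfx, nav_env)
  expect_true(cls$in_goal_area[1])    # goal-area panel
  expect_false(cls$in_goal_area[2])   # opposite wall
  expect_true(cls$in_goal_area[3])    # floor inside the goal-area polygon
  expect_false(cls$in_goal_area[4])   # floor 3+ m from the goal zone
  expect_equal(goal_fixation_proportion(cls), 0.5)
})

test_that("goal-fixation proportion handles the empty case", {
  empty <- data.frame(t_start = numeric(0), t_end = numeric(0),
                      duration_ms = numeric(0), x = numeric(0),
                      y = numeric(0), z = numeric(0),
                      surface_id = character(0), in_goal_area = logical(0))
  expect_warning(p <- goal_fixation_proportion(empty),
                 class = "navpace_no_fixations")
  expect_true(is.na(p))
  ten <- data.frame(in_goal_area = c(rep(TRUE, 3), rep(FALSE, 7)))
  expect_equal(goal_fixation_proportion(ten), 0.3)
  expect_equal(goal_fixation_proportion(data.frame(in_goal_area = rep(TRUE, 4))), 1)
})
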