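simple_params <- function(d = 0.8, v = 1.1, p = 0.3, n = 2, ...) {
  navigator_params(speeds = rep(v, n), directness = rep(d, n),
                   goal_fix_prob = rep(p, n), ...)
}

test_that("identical seeds reproduce recordings bit-identically", {
  p <- simple_params()
  a <- generate_trial(nav_env, p, 1, seed = 7)
  b <- generate_trial(nav_env, p, 1, seed = 7)
  expect_identical(a$recording$markers$positions,
                   b$recording$markers$positions)
  expect_identical(a$recording$gaze$directions, b$recording$gaze$directions)
  expect_identical(a$truth, b$truth)
  c_ <- generate_trial(nav_env, p, 1, seed = 8)
  expect_false(identical(a$recording$markers$positions,
                         c_$recording$markers$positions))
})

test_that("programmed directness maps to the walked path by construction", {
  D <- function(start) sqrt(sum((nav_env$goal_zone$center - start)^2))
  for (d in c(0.45, 0.7, 0.9, 1.0)) {
    p <- simple_params(d = d)
    g <- generate_trial(nav_env, p, 1, seed = 30 + round(100 * d),
                        include_gaze = FALSE)
    path <- g$truth$path
    len <- oracle_arclength(path)
    # truncated arc length is calibrated to start-to-center distance over
    # directness, so the true efficiency equals the programmed directness
    expect_equal(D(path[1, ]) / len, d, tolerance = 0.02)
    if (d == 1.0) expect_equal(len, D(path[1, ]), tolerance = 0.02)
  }
})

test_that("goal-fixation probability 0 yields no goal fixations", {
  p <- simple_params(p = 0)
  g <- generate_trial(nav_env, p, 1, seed = 11)
  expect_equal(g$truth$goal_fix_proportion, 0)
  expect_false(any(g$truth$fixations$in_goal))
})

test_that("infeasible directness from a start position raises an error", {
  p <- navigator_params(speeds = 1, directness = 0.18, goal_fix_prob = 0,
                        start_positions = rbind(c(6.5, 1.1)))
  expect_error(generate_trial(nav_env, p, 1, seed = 1), "incompatible")
})

test_that("cohort shape follows the group specs", {
  co <- generate_cohort(nav_env, n_per_group = 14, n_trials = 8, seed = 2,
                        trials = integer(0), include_gaze = FALSE,
                        n_extra_older = 0)
  expect_length(co$participants, 28L)
  n_trials <- vapply(co$participants, function(p) p$n_trials, integer(1))
  expect_true(all(n_trials == 8L))
  co2 <- navpace:::draw_cohort_params(2, 14, 8, n_extra_older = 2)
  expect_equal(sum(vapply(co2, function(p) p$n_trials, integer(1))), 226L)
})

test_that("zero between-participant variance collapses same-group params", {
  tpl <- group_template("young", 4, speed_sd = 0, slowdown_sd = 0,
                        d1_sd = 0, dmax_sd = 0, pmax_sd = 0,
                        step_freq_sd = 0, orientation_sd = 0,
                        speed_trial_jitter = 1e-12, te_trial_jitter = 1e-12)
  specs <- navpace:::draw_cohort_params(5, 3, 4, young = tpl,
                                        older = group_template("older", 4),
                                        n_extra_older = 0)
  young <- Filter(function(s) s$group == "young", specs)
  expect_equal(young[[1]]$params$speeds, young[[2]]$params$speeds)
  expect_equal(young[[2]]$params$directness, young[[3]]$params$directness)
})

test_that("programmed older-group slowdown averages to its template mean", {
  changes <- unlist(lapply(1:30, function(s) {
    specs <- navpace:::draw_cohort_params(400 + s, 14, 8, n_extra_older = 0)
    older <- Filter(function(sp) sp$group == "older", specs)
    vapply(older, function(sp) {
      v <- sp$params$speeds
      100 * (v[length(v)] - v[1]) / v[length(v)]
    }, numeric(1))
  }))
  expect_equal(mean(changes), 20, tolerance = 0.1 * 20 + 2)
})

test_that("trial subsets reproduce the corresponding full-cohort trials", {
  full <- generate_cohort(nav_env, n_per_group = 2, n_trials = 4, seed = 9,
                          include_gaze = FALSE, n_extra_older = 0)
  sub <- generate_cohort(nav_env, n_per_group = 2, n_trials = 4, seed = 9,
                         trials = c(1, 4), include_gaze = FALSE,
                         n_extra_older = 0)
  for (i in seq_along(full$participants)) {
    expect_identical(sub$participants[[i]]$trials[["1"]]$recording$markers,
                     full$participants[[i]]$trials[["1"]]$recording$markers)
    expect_identical(sub$participants[[i]]$trials[["4"]]$recording$markers,
                     full$participants[[i]]$trials[["4"]]$recording$markers)
  }
})

test_that("ground-truth heel strikes sit at downward-to-upward crossings", {
  p <- simple_params(d = 0.95, noise_pos = 0)
  g <- generate_trial(nav_env, p, 1, seed = 13, include_gaze = FALSE)
  mk <- g$recording$markers
  truth <- g$truth$strikes
  for (foot in c("left", "right")) {
    z <- mk$positions[[paste0(foot, "_heel")]][, 3]
    vz <- velocity(mk$times, z)
    tk <- truth$time[truth$foot == foot]
    for (t_ev in tk) {
      i <- which.min(abs(mk$times - t_ev))
      lo <- max(1, i - 2); hi <- min(length(vz), i + 2)
      expect_true(any(vz[lo:hi] <= 0) && any(vz[lo:hi] >= 0))
    }
  }
})
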