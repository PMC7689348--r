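cfg0 <- analysis_config()

test_that("zero-phase low-pass preserves DC and the passband, kills the stopband", {
  rate <- 120
  t <- seq(0, 5, by = 1 / rate)
  expect_lt(max(abs(lowpass(rep(2.5, length(t)), 10, 2, rate = rate) - 2.5)),
            1e-9)
  s1 <- sin(2 * pi * 1 * t)
  f1 <- lowpass(s1, 10, 2, rate = rate)
  mid <- seq(rate, length(t) - rate)
  expect_equal(max(abs(f1[mid])), 1, tolerance = 0.01)
  s50 <- sin(2 * pi * 50 * t)
  f50 <- lowpass(s50, 10, 2, rate = rate)
  expect_lt(max(abs(f50[mid])), 0.05)
  expect_error(lowpass(rnorm(5), 10, 2, rate = rate), "short")
  expect_error(lowpass(rnorm(100), 70, 2, rate = rate), "twice the cutoff")
})

test_that("heel strikes land at analytic zero crossings of a sinusoid", {
  f <- 1; A <- 0.05; rate <- 120
  t <- seq(0, 2 / f, by = 1 / rate)
  z <- A / (2 * pi * f) * cos(2 * pi * f * t)  # v_z = -A sin(2 pi f t)
  ev <- detect_heel_strikes(t, z, foot = "left", cfg = cfg0)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$time, c(0.5, 1.5), tolerance = 1 / rate)
  rising <- detect_heel_strikes(t, 0.001 * t, foot = "left", cfg = cfg0)
  expect_equal(nrow(rising), 0L)
})

test_that("detector matches the exhaustive sign-change oracle on random traces", {
  set.seed(101)
  for (k in 1:50) {
    tr <- random_vz_trace(sample(50:500, 1))
    got <- navpace:::strike_times_impl(tr$times, tr$vz, cfg0)
    want <- oracle_heel_strikes(tr$times, tr$vz, cfg0)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("standing detection finds maximal slow intervals", {
  rate <- 120
  t <- seq(0, 4, by = 1 / rate)
  still <- cbind(1 + 0 * t, 2 + 0 * t)
  st <- detect_standing(t, still, cfg0)
  expect_equal(nrow(st), 1L)
  expect_equal(c(st$t_start, st$t_end), range(t))
  walk <- cbind(t * 1.0, 0 * t)
  expect_equal(nrow(detect_standing(t, walk, cfg0)), 0L)
  # walk 1.5 s - pause 1 s - walk
  x <- c(seq(0, 1.5, by = 1 / rate), rep(1.5, rate),
         seq(1.5, 3, by = 1 / rate)[-1])
  tt <- seq_along(x) / rate
  st2 <- detect_standing(tt, cbind(x, 0 * x), cfg0)
  expect_equal(nrow(st2), 1L)
  expect_equal(st2$t_end - st2$t_start, 1, tolerance = 3 / rate)
})

test_that("phases split at the first step event", {
  ev <- data.frame(time = c(2.4, 3.0), foot = c("left", "right"))
  ph <- split_phases(ev, 10)
  expect_equal(ph$orientation, c(0, 2.4))
  expect_equal(ph$navigation, c(2.4, 10))
  ph0 <- split_phases(data.frame(time = 0, foot = "left"), 5)
  expect_equal(diff(ph0$orientation), 0)
  expect_error(split_phases(data.frame(time = numeric(0),
                                       foot = character(0)), 5),
               "no navigation phase")
  # synthetic trial: recovered boundary within one sample of ground truth
  p <- navigator_params(speeds = 1.1, directness = 0.9, goal_fix_prob = 0,
                        noise_pos = 1e-4)
  g <- generate_trial(nav_env, p, 1, seed = 21, include_gaze = FALSE)
  det <- analyze_trial(g$recording, nav_env, gaze = FALSE, detail = TRUE)
  expect_equal(det$phases$navigation[1], g$truth$first_step,
               tolerance = 1.5 / 120)
})

test_that("heading follows the axis convention and analytic turn rates", {
  rate <- 120
  t <- seq(0, 3, by = 1 / rate)
  hx <- heading_series(cbind(t * 1.2, 0 * t), cfg0, times = t)
  expect_equal(stats::median(hx$heading, na.rm = TRUE), 0, tolerance = 1e-6)
  hy <- heading_series(cbind(0 * t, t * 1.2), cfg0, times = t)
  expect_equal(stats::median(hy$heading, na.rm = TRUE), 90, tolerance = 1e-6)
  r <- 2; v <- 1.0
  th <- v * t / r
  hc <- heading_series(cbind(r * cos(th), r * sin(th)), cfg0, times = t)
  rate_deg <- diff(hc$heading[100:200]) * rate     # deg per second
  expect_equal(mean(rate_deg) * pi / 180, v / r, tolerance = 0.02 * v / r)
})

test_that("heading is masked while standing", {
  t <- seq(0, 3, by = 1 / 120)
  h <- heading_series(cbind(0.001 * t, 0 * t), cfg0, times = t)
  expect_true(all(is.na(h$heading)))
})

test_that("straightness classification is strict at the threshold", {
  rate <- 16                         # dyadic grid: exact event-time lookups
  t <- seq(0, 5, by = 1 / rate)
  ev <- data.frame(time = seq(0.5, 4.5, by = 0.5),
                   foot = rep(c("left", "right"), length.out = 9))
  body <- cbind(1.2 * t, 0 * t)
  mk_heading <- function(deg_per_step) {
    data.frame(time = t, heading = deg_per_step * t / 0.5,
               speed = rep(1.2, length(t)))
  }
  all_straight <- segment_and_classify_steps(ev, mk_heading(0), body, t, cfg0)
  expect_true(all(all_straight$straight))
  expect_equal(nrow(all_straight), 8L)
  turn60 <- segment_and_classify_steps(ev, mk_heading(60), body, t, cfg0)
  expect_false(any(turn60$straight))
  just_below <- segment_and_classify_steps(ev, mk_heading(44.9), body, t, cfg0)
  expect_true(all(just_below$straight))
  at_45 <- segment_and_classify_steps(ev, mk_heading(45), body, t, cfg0)
  expect_false(any(at_45$straight))
})

test_that("same-foot double strikes break the step sequence", {
  t <- seq(0, 4, by = 0.01)
  ev <- data.frame(time = c(0.5, 1.0, 1.5, 2.0, 2.5),
                   foot = c("left", "right", "right", "left", "right"))
  h <- data.frame(time = t, heading = 0 * t, speed = rep(1, length(t)))
  st <- segment_and_classify_steps(ev, h, cbind(t, 0 * t), t, cfg0)
  expect_equal(nrow(st), 3L)  # the right->right interval is dropped
})

test_that("rotating the room frame shifts headings and keeps classification", {
  p <- navigator_params(speeds = 1.1, directness = 0.75, goal_fix_prob = 0)
  g <- generate_trial(nav_env, p, 1, seed = 33, include_gaze = FALSE)
  mk <- g$recording$markers
  phi <- 50 * pi / 180
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  rot <- mk
  rot$positions <- lapply(mk$positions, function(m) {
    m2 <- m
    m2[, 1:2] <- m[, 1:2] %*% t(R)
    m2
  })
  h1 <- heading_series(mk, cfg0)
  h2 <- heading_series(rot, cfg0)
  ok <- !is.na(h1$heading) & !is.na(h2$heading)
  dh <- ((h2$heading[ok] - h1$heading[ok] - 50 + 180) %% 360) - 180
  expect_lt(stats::median(abs(dh)), 1e-6)
})

test_that("trial walking speed is a median over interior straight steps", {
  steps <- data.frame(t_start = seq(0, 2, by = 0.5),
                      t_end = seq(0.5, 2.5, by = 0.5),
                      foot_start = rep(c("left", "right"), length.out = 5),
                      foot_end = rep(c("right", "left"), length.out = 5),
                      heading_start = 0, heading_end = 0, heading_change = 0,
                      straight = c(TRUE, TRUE, TRUE, TRUE, TRUE),
                      speed = c(9, 1.0, 1.2, 5.0, 9))
  ws <- trial_walking_speed(steps, cfg0)
  expect_equal(as.numeric(ws), 1.2)
  expect_equal(attr(ws, "n_eligible"), 3L)
  only_first <- steps[1, ]
  expect_warning(ws2 <- trial_walking_speed(only_first, cfg0),
                 class = "navpace_insufficient_steps")
  expect_true(is.na(ws2))
})

test_that("straight fraction counts straight-step coverage of navigation", {
  steps <- data.frame(t_start = c(1, 2, 3), t_end = c(2, 3, 4),
                      straight = c(TRUE, FALSE, TRUE), speed = 1)
  ph <- list(orientation = c(0, 1), navigation = c(1, 5))
  expect_equal(straight_fraction(steps, ph), 0.5)
  steps$straight <- TRUE
  expect_equal(straight_fraction(steps, ph), 0.75)
  steps$straight <- FALSE
  expect_equal(straight_fraction(steps, ph), 0)
})

test_that("goal-border crossing is interpolated on the Chebyshev boundary", {
  t <- seq(0, 10, by = 1 / 120)
  # straight walk along +x through the goal center's y
  ctr <- nav_env$goal_zone$center
  xy <- cbind(t * 0.5, rep(ctr[2], length(t)))
  tc <- detect_goal_crossing(t, xy, nav_env)
  expect_equal(0.5 * tc, ctr[1] - 0.4, tolerance = 1e-6)
  away <- cbind(6 + 0 * t, 1 + 0 * t)
  expect_true(is.na(detect_goal_crossing(t, away, nav_env)))
})
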