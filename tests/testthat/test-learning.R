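cfgl <- analysis_config()

test_that("trajectory efficiency is straight distance over walked length", {
  straight <- cbind(seq(0, 4, length.out = 50), rep(0, 50))
  expect_equal(trajectory_efficiency(straight, c(0, 0), c(4, 0)), 1,
               tolerance = 1e-9)
  lpath <- rbind(c(0, 0), c(0, 3), c(4, 3))
  expect_equal(trajectory_efficiency(lpath, c(0, 0), c(4, 3)), 5 / 7,
               tolerance = 1e-12)
  # stopping at the goal border, short of the center: efficiency above 1
  short <- rbind(c(0, 0), c(3.6, 0))
  expect_equal(trajectory_efficiency(short, c(0, 0), c(4, 0)), 4 / 3.6,
               tolerance = 1e-12)
  expect_error(trajectory_efficiency(rbind(c(1, 1), c(1, 1)), c(0, 0),
                                     c(1, 0)), "zero-length")
  expect_error(trajectory_efficiency(rbind(c(1, 1)), c(0, 0), c(1, 0)),
               "two points")
})

test_that("trajectory efficiency agrees with an arc-length oracle", {
  set.seed(12)
  for (k in 1:20) {
    path <- cbind(cumsum(runif(30, 0.05, 0.3)), cumsum(rnorm(30, 0, 0.2)))
    te <- trajectory_efficiency(path, path[1, ], c(8, 2))
    expect_equal(te, sqrt(sum((c(8, 2) - path[1, ])^2)) /
                   oracle_arclength(path), tolerance = 1e-9)
  }
})

test_that("criterion trial requires two consecutive trials above criterion", {
  expect_equal(criterion_trial(c(0.5, 0.9, 0.9, 0.95)), 2L)
  expect_equal(criterion_trial(c(0.9, 0.8, 0.9, 0.9)), 3L)
  expect_equal(criterion_trial(c(0.9, 0.9)), 1L)
  # strict inequality at the criterion
  expect_warning(n <- criterion_trial(c(0.85, 0.85, 0.85)),
                 class = "navpace_criterion_fallback")
  expect_equal(n, 3L)
  expect_error(criterion_trial(0.9), "two trials")
})

test_that("criterion trial matches a brute-force pair scan on random curves", {
  set.seed(31)
  for (k in 1:2000) {
    te <- runif(sample(2:9, 1), 0.5, 1.0)
    got <- suppressWarnings(criterion_trial(te))
    expect_identical(got, oracle_criterion(te, 0.85))
  }
})

test_that("control profile averages young scores per trial, skipping NA", {
  expect_equal(control_profile(rbind(c(1.0, 0.8), c(0.6, 1.0))), c(0.8, 0.9))
  expect_equal(control_profile(rbind(c(0.7, 0.9))), c(0.7, 0.9))
  with_na <- rbind(c(1.0, NA, 0.9), c(0.6, 0.8, 0.7))
  expect_equal(control_profile(with_na), c(0.8, 0.8, 0.8))
  expect_error(control_profile(rbind(c(1, NA), c(1, NA))), "trial")
})

test_that("multipliers are C1/Ci with the first set to zero", {
  expect_equal(multipliers(c(2, 4, 1)), c(0, 0.5, 2))
  expect_equal(multipliers(rep(3, 5)), c(0, 1, 1, 1, 1))
  expect_equal(multipliers(7), 0)
  expect_error(multipliers(c(1, 0, 2)), "zero")
})

test_that("adaptation index sums M_i S_i up to the criterion trial", {
  M <- multipliers(c(2, 1, 1))
  expect_equal(adaptation_index(c(2, 1, 1), M, 3), 4)
  expect_equal(adaptation_index(c(5, 1, 1), M, 1), 0)
  expect_equal(adaptation_index(c(5, 0, 0), multipliers(c(1, 1, 1)), 3), 0)
  expect_error(adaptation_index(c(1, NA, 1), M, 3), "missing")
  # control self-consistency: S = C gives (n-1) * C1, exactly
  set.seed(4)
  for (k in 1:25) {
    C <- runif(sample(3:9, 1), 0.3, 1.4)
    n <- sample(2:length(C), 1)
    expect_equal(adaptation_index(C, multipliers(C), n), (n - 1) * C[1])
  }
})

test_that("adaptation index is scale-equivariant", {
  set.seed(9)
  C <- runif(6, 0.4, 1.2); S <- runif(6, 0.4, 1.2)
  base <- adaptation_index(S, multipliers(C), 5)
  for (k in c(0.1, 2, 13)) {
    expect_equal(adaptation_index(k * S, multipliers(k * C), 5), k * base,
                 tolerance = 1e-12)
  }
})

test_that("percent change in walking speed follows the printed formula", {
  expect_equal(change_in_walking_speed(1.0, 1.0), 0)
  expect_equal(change_in_walking_speed(0.8, 1.0), 20, tolerance = 1e-12)
  expect_equal(change_in_walking_speed(1.2, 1.0), -20, tolerance = 1e-12)
  expect_error(change_in_walking_speed(1, 0), "positive")
})

test_that("reference trial selection falls back to the penultimate trial", {
  cfg <- cfgl
  ws <- c(1.0, 1.1, 1.2, 1.15)
  ok <- select_reference_trial(ws, c(5, 6, 6, 5), c(0.6, 0.9, 0.9, 0.9), cfg)
  expect_equal(ok$trial, 4L)
  expect_equal(ok$ws_ref, 1.15)
  # last trial has one straight step, penultimate above criterion
  fb <- select_reference_trial(ws, c(5, 6, 6, 1), c(0.6, 0.9, 0.9, 0.9), cfg)
  expect_equal(fb$trial, 3L)
  expect_equal(fb$ws_ref, 1.2)
  # last invalid and penultimate below criterion: missing with warning
  expect_warning(
    none <- select_reference_trial(ws, c(5, 6, 6, 1), c(0.6, 0.9, 0.7, 0.9),
                                   cfg),
    class = "navpace_no_reference_trial")
  expect_true(is.na(none$trial))
})

test_that("cohort adaptation results integrate the per-trial metrics", {
  te_y <- c(0.6, 0.8, 0.88, 0.9)
  mk <- function(pid, group, ws, ws_n, te, nt = 4) {
    data.frame(participant_id = pid, group = group, trial_index = seq_len(nt),
               walking_speed = ws, ws_n_steps = ws_n,
               trajectory_efficiency = te,
               goal_fixation_proportion = seq(0.1, 0.4, length.out = nt))
  }
  metrics <- rbind(
    mk("Y1", "young", c(1.2, 1.3, 1.3, 1.3), c(6, 6, 6, 6), te_y),
    mk("Y2", "young", c(1.1, 1.2, 1.25, 1.3), c(6, 6, 6, 6), te_y + 0.02),
    # older participant with 5 trials: control profile extends C5 := C4
    mk("O1", "older", c(0.8, 0.9, 1.0, 1.05, 1.1), c(6, 6, 6, 6, 6),
       c(0.5, 0.7, 0.86, 0.9, 0.9), nt = 5),
    # older participant whose last trial is invalid -> penultimate reference
    mk("O2", "older", c(0.9, 1.0, 1.1, 1.05), c(6, 6, 6, 1),
       c(0.5, 0.7, 0.9, 0.9)))
  ad <- adaptation_results(metrics, cfg = cfgl)
  expect_equal(ad$criterion_trial[ad$participant_id == "Y1"], 3L)
  expect_equal(ad$reference_trial[ad$participant_id == "O1"], 5L)
  expect_equal(ad$reference_trial[ad$participant_id == "O2"], 3L)
  expect_equal(ad$change_ws[ad$participant_id == "O2"],
               100 * (1.1 - 0.9) / 1.1, tolerance = 1e-12)
  # hand-check one adaptation index against the definition
  C <- colMeans(rbind(te_y, te_y + 0.02))
  M <- c(0, C[1] / C[2], C[1] / C[3], C[1] / C[4])
  S <- c(0.5, 0.7, 0.86, 0.9, 0.9)
  expect_equal(ad$ai_te[ad$participant_id == "O1"],
               sum(M[2:3] * S[2:3]), tolerance = 1e-12)
})
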