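test_that("default environment matches the instrumented room layout", {
  env <- nav_env
  panels <- setdiff(names(env$surfaces), "floor")
  expect_length(panels, 19L)
  expect_true("floor" %in% names(env$surfaces))
  expect_equal(env$goal_zone$side, 0.8)
  half <- env$goal_zone$side / 2
  expect_true(env$goal_zone$center[1] - half >= 0 &&
                env$goal_zone$center[1] + half <= env$room_length)
  expect_true(all(env$goal_area_surface_ids %in% names(env$surfaces)))
  expect_true("floor" %in% env$goal_area_surface_ids)
})

test_that("minimal config applies defaults; goal zone scales with the room", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("room_length: 6.0", "room_width: 4.0"), path)
  env <- load_environment(path)
  expect_equal(env$room_length, 6.0)
  expect_equal(env$goal_zone$side, 0.8)
  expect_equal(env$goal_zone$center, c(1.5, 3.0))
})

test_that("geometry validation rejects malformed environments", {
  expect_error(environment_model(goal_center = c(9, 2)), "goal zone")
  expect_error(environment_model(goal_center = c(2, 4.25)), "goal zone")
  expect_error(environment_model(goal_area_surface_ids = c("panel_n1", "ghost")),
               "ghost")
  bad <- list(list(id = "warped",
                   vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0.01),
                                    c(0, 1, 0))))
  expect_error(environment_model(surfaces = bad,
                                 goal_area_surface_ids = character(0)),
               "warped")
})

test_that("environment YAML round-trip is lossless", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_environment(nav_env, path)
  env2 <- load_environment(path)
  expect_equal(env2$room_length, nav_env$room_length, tolerance = 1e-9)
  expect_equal(env2$goal_zone$center, nav_env$goal_zone$center,
               tolerance = 1e-9)
  expect_setequal(names(env2$surfaces), names(nav_env$surfaces))
  for (id in names(nav_env$surfaces)) {
    expect_equal(env2$surfaces[[id]]$vertices, nav_env$surfaces[[id]]$vertices,
                 tolerance = 1e-9)
  }
  expect_setequal(env2$goal_area_surface_ids, nav_env$goal_area_surface_ids)
})

test_that("analysis config validates its invariants", {
  cfg <- analysis_config()
  expect_equal(cfg$filter_cutoff, 10)
  expect_equal(cfg$straight_threshold, 45)
  expect_equal(cfg$min_fixation, 100)
  expect_equal(cfg$dispersion_k, 2)
  expect_equal(cfg$efficiency_criterion, 0.85)
  expect_error(analysis_config(min_fixation = -5), "positive")
  expect_error(analysis_config(efficiency_criterion = 1.2), "\\(0, 1\\)")
})
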