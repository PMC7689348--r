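# End-to-end orchestration: per-trial analysis, cohort tables, the
# statistical layer, and a reproducible config-driven run with manifest.

#' Analyze one trial recording
#'
#' Runs the full processing chain on a `trial_recording`: zero-phase
#' low-pass filtering, standing detection, heel-strike detection, phase
#' split, heading, step segmentation/classification, per-trial walking
#' speed, trajectory efficiency on the body-reference polyline truncated at
#' the goal-border crossing, and (optionally) gaze resampling, surface
#' intersection, fixation detection and goal-fixation proportion.
#'
#' @param rec a `trial_recording`.
#' @param env a `nav_environment`.
#' @param cfg an [analysis_config()].
#' @param gaze process the gaze stream (if present).
#' @param detail also return the step and fixation tables.
#' @return a one-row data frame of trial metrics (see
#'   [adaptation_results()] for the column contract); with `detail = TRUE`,
#'   a list `(metrics, steps, fixations, phases)`.
#' @export
analyze_trial <- function(rec, env, cfg = analysis_config(), gaze = TRUE,
                          detail = FALSE) {
  res <- analyze_trial_impl(rec, env, cfg, gaze)
  metrics <- as.data.frame(res$metrics, stringsAsFactors = FALSE)
  if (!detail) return(metrics)
  list(metrics = metrics, steps = res$steps, fixations = res$fixations,
       phases = res$phases, standing = as.data.frame(res$standing),
       events = res$events)
}

# core of analyze_trial; returns the metrics row as a plain list
analyze_trial_impl <- function(rec, env, cfg, gaze = TRUE) {
  stopifnot(inherits(rec, "trial_recording"), inherits(env, "nav_environment"))
  mk <- rec$markers
  require_markers(mk, c(HEEL_LEFT, HEEL_RIGHT, EYE_FRAME))
  times <- mk$times
  ba <- butter_coef(cfg$filter_cutoff, cfg$filter_order, mk$rate)
  ctr_raw <- (mk$positions[[EYE_FRAME[1]]] + mk$positions[[EYE_FRAME[2]]] +
                mk$positions[[EYE_FRAME[3]]] + mk$positions[[EYE_FRAME[4]]]) / 4
  filt <- zerophase_mat(cbind(ctr_raw[, 1], ctr_raw[, 2],
                              mk$positions[[HEEL_LEFT]][, 3],
                              mk$positions[[HEEL_RIGHT]][, 3]),
                        ba$b, ba$a, mk$rate, cfg$filter_cutoff)
  ctr <- ctr_raw
  ctr[, 1] <- filt[, 1]
  ctr[, 2] <- filt[, 2]
  zl <- filt[, 3]
  zr <- filt[, 4]
  v_ctr <- velocity(times, ctr[, 1:2, drop = FALSE])
  speed_ctr <- sqrt(v_ctr[, 1]^2 + v_ctr[, 2]^2)
  standing <- standing_impl(times, cfg = cfg, speed = speed_ctr)

  t_end <- rec$trial_end_time
  if (is.na(t_end)) t_end <- detect_goal_crossing(times, ctr[, 1:2], env)
  if (is.na(t_end)) t_end <- times[length(times)]

  ev_l <- strike_times_impl(times, velocity(times, zl), cfg, standing)
  ev_r <- strike_times_impl(times, velocity(times, zr), cfg, standing)
  ev_t <- c(ev_l, ev_r)
  ev_f <- rep(c("left", "right"), c(length(ev_l), length(ev_r)))
  in_trial <- ev_t <= t_end + 1e-9
  o <- order(ev_t[in_trial])
  ev <- list(time = ev_t[in_trial][o], foot = ev_f[in_trial][o])

  heading <- list(time = times,
                  heading = unwrap_deg({
                    h <- atan2(v_ctr[, 2], v_ctr[, 1]) * 180 / pi
                    h[speed_ctr < cfg$standing_speed_threshold] <- NA_real_
                    h
                  }),
                  speed = speed_ctr)
  steps <- segment_and_classify_steps(ev, heading, ctr[, 1:2], times, cfg)
  ws <- NA_real_; ws_n <- 0L
  if (nrow(steps) > 0) {
    ws <- withCallingHandlers(trial_walking_speed(steps, cfg),
                              navpace_insufficient_steps = function(w)
                                invokeRestart("muffleWarning"))
    ws_n <- attr(ws, "n_eligible") %||% 0L
  }
  phases <- if (length(ev$time) > 0) split_phases(ev, t_end) else NULL
  sf <- if (!is.null(phases) && nrow(steps) > 0)
    straight_fraction(steps, phases) else NA_real_

  keep <- times <= t_end
  poly <- ctr[keep, 1:2, drop = FALSE]
  if (any(!keep)) {
    xe <- stats::approx(times, ctr[, 1], xout = t_end)$y
    ye <- stats::approx(times, ctr[, 2], xout = t_end)$y
    poly <- rbind(poly, c(xe, ye))
  }
  start <- rec$start_position
  if (anyNA(start)) start <- poly[1, ]
  te <- trajectory_efficiency(poly, start, env$goal_zone$center)

  gf <- NA_real_; n_fix <- NA_integer_; fixs <- NULL
  if (gaze && !is.null(rec$gaze)) {
    rg <- resample_gaze(rec$gaze, target_times = times,
                        max_gap = cfg$max_gaze_gap)
    gp <- intersect_gaze(rg, env)
    fixs <- detect_fixations(gp, cfg)
    if (cfg$fixations_navigation_only && !is.null(phases)) {
      mid <- (fixs$t_start + fixs$t_end) / 2
      fixs <- fixs[mid >= phases$navigation[1], , drop = FALSE]
    }
    fixs <- classify_goal_fixations(fixs, env)
    n_fix <- nrow(fixs)
    gf <- withCallingHandlers(goal_fixation_proportion(fixs),
                              navpace_no_fixations = function(w)
                                invokeRestart("muffleWarning"))
  }
  metrics <- list(
    participant_id = rec$participant_id, group = rec$group,
    trial_index = rec$trial_index,
    walking_speed = as.numeric(ws), ws_n_steps = as.integer(ws_n),
    trajectory_efficiency = te,
    goal_fixation_proportion = as.numeric(gf), n_fixations = as.integer(n_fix),
    straight_fraction = sf, n_steps = nrow(steps),
    first_step_time = if (!is.null(phases)) phases$navigation[1] else NA_real_,
    trial_end_time = t_end)
  list(metrics = metrics, steps = steps, fixations = fixs, phases = phases,
       standing = standing, events = ev)
}

# assemble a data frame from a list of homogeneous plain-list rows
rows_to_df <- function(rows) {
  cols <- names(rows[[1]])
  out <- lapply(cols, function(cn) unlist(lapply(rows, `[[`, cn),
                                          use.names = FALSE))
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Analyze every trial of a cohort
#'
#' @param cohort a `nav_cohort` from [generate_cohort()], or a list of
#'   `trial_recording`s.
#' @param cfg an [analysis_config()].
#' @param gaze process gaze streams.
#' @return tidy per-trial metrics data frame (one row per trial).
#' @export
analyze_cohort <- function(cohort, cfg = analysis_config(), gaze = TRUE) {
  recs <- if (inherits(cohort, "nav_cohort")) {
    env <- cohort$env
    unlist(lapply(cohort$participants, function(p)
      lapply(p$trials, `[[`, "recording")), recursive = FALSE)
  } else {
    stop_nav("analyze_cohort expects a nav_cohort; for plain recordings use ",
             "analyze_trial per recording")
  }
  rows <- lapply(recs, analyze_trial, env = env, cfg = cfg, gaze = gaze)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate and analyze a synthetic cohort without storing recordings
#'
#' Streams trial generation and analysis (one trial in memory at a time);
#' used for replicate studies. Seeding is identical to [generate_cohort()],
#' so the metrics equal those of an analyzed stored cohort.
#'
#' @inheritParams generate_cohort
#' @param cfg an [analysis_config()].
#' @param gaze generate and analyze gaze streams.
#' @return list with `metrics` (per-trial analysis table) and `truth`
#'   (programmed per-trial values, incl. `true_change_ws`).
#' @export
simulate_cohort_metrics <- function(env, n_per_group = 14L, n_trials = 8L,
                                    seed = 1L,
                                    young = group_template("young", n_trials),
                                    older = group_template("older", n_trials),
                                    trials = NULL, gaze = TRUE,
                                    n_extra_older = 2L, coupling_rho = NULL,
                                    cfg = analysis_config()) {
  specs <- draw_cohort_params(seed, n_per_group, n_trials, young, older,
                              n_extra_older, coupling_rho)
  mrows <- list(); trows <- list()
  for (sp in specs) {
    idx <- seq_len(sp$n_trials)
    if (!is.null(trials)) idx <- intersect(trials, idx)
    spd <- sp$params$speeds
    change_true <- 100 * (spd[length(spd)] - spd[1]) / spd[length(spd)]
    for (ti in idx) {
      g <- generate_trial(env, sp$params, ti,
                          seed = derive_seed(seed, sp$group_index, sp$p_index, ti),
                          include_gaze = gaze,
                          participant_id = sp$participant_id, group = sp$group)
      mrows[[length(mrows) + 1L]] <-
        analyze_trial_impl(g$recording, env, cfg, gaze = gaze)$metrics
      trows[[length(trows) + 1L]] <- list(
        participant_id = sp$participant_id, group = sp$group,
        trial_index = ti, true_speed = g$truth$speed,
        true_efficiency = g$truth$efficiency,
        goal_fix_prob = g$truth$goal_fix_prob,
        true_goal_fix_proportion = g$truth$goal_fix_proportion,
        true_change_ws = change_true)
    }
  }
  list(metrics = rows_to_df(mrows), truth = rows_to_df(trows))
}

#' Simulate per-participant change-in-walking-speed scores
#'
#' Runs the kinematics pipeline on the trials that determine the
#' walking-speed change score: the first and last trials, plus the
#' penultimate trial when the last trial's walking speed is invalid (the
#' reference-trial fallback). Seeding matches [generate_cohort()] trial for
#' trial, so the scores equal those computed from a fully generated cohort.
#'
#' @inheritParams simulate_cohort_metrics
#' @return data frame with one row per participant: `participant_id`,
#'   `group`, `change_ws`, `reference_trial`, `true_change_ws` (programmed).
#' @export
simulate_change_scores <- function(env, n_per_group = 14L, n_trials = 8L,
                                   seed = 1L,
                                   young = group_template("young", n_trials),
                                   older = group_template("older", n_trials),
                                   n_extra_older = 2L,
                                   cfg = analysis_config()) {
  specs <- draw_cohort_params(seed, n_per_group, n_trials, young, older,
                              n_extra_older, NULL)
  rows <- lapply(specs, function(sp) {
    T_p <- sp$n_trials
    one <- function(ti) {
      g <- generate_trial(env, sp$params, ti,
                          seed = derive_seed(seed, sp$group_index,
                                             sp$p_index, ti),
                          include_gaze = FALSE,
                          participant_id = sp$participant_id, group = sp$group)
      analyze_trial_impl(g$recording, env, cfg, gaze = FALSE)$metrics
    }
    ws <- rep(NA_real_, T_p); ws_n <- rep(0L, T_p); te <- rep(NA_real_, T_p)
    put <- function(ti, m) {
      ws[ti] <<- m$walking_speed; ws_n[ti] <<- m$ws_n_steps
      te[ti] <<- m$trajectory_efficiency
    }
    put(1L, one(1L))
    put(T_p, one(T_p))
    if (!(!is.na(ws[T_p]) && ws_n[T_p] >= cfg$min_eligible_steps)) {
      put(T_p - 1L, one(T_p - 1L))
    }
    ref <- withCallingHandlers(
      select_reference_trial(ws, ws_n, te, cfg),
      navpace_no_reference_trial = function(w) invokeRestart("muffleWarning"))
    change <- NA_real_
    if (!is.na(ref$trial) && !is.na(ws[1]) &&
          ws_n[1] >= cfg$min_eligible_steps) {
      change <- change_in_walking_speed(ws[1], ref$ws_ref)
    }
    spd <- sp$params$speeds
    list(participant_id = sp$participant_id, group = sp$group,
         change_ws = change, reference_trial = ref$trial,
         true_change_ws = 100 * (spd[length(spd)] - spd[1]) / spd[length(spd)])
  })
  rows_to_df(rows)
}

#' Group comparisons and correlations for a cohort
#'
#' Compares the age groups on the per-participant means of the three basic
#' variables (walking speed, trajectory efficiency, goal fixations) and on
#' the dependent variables (change in walking speed, three adaptation
#' indices), using the assumption-gated test; correlates the adaptation
#' index of walking speed with those of trajectory efficiency and goal
#' fixations (Bonferroni family of 2).
#'
#' @param metrics per-trial metrics table.
#' @param adaptation per-participant table from [adaptation_results()].
#' @param cfg an [analysis_config()].
#' @param correlation_method `"pearson"` or `"spearman"`.
#' @return list with data frames `comparisons` and `correlations`.
#' @export
cohort_statistics <- function(metrics, adaptation, cfg = analysis_config(),
                              correlation_method = "pearson") {
  pmean <- function(col) {
    agg <- stats::aggregate(metrics[[col]],
                            by = list(participant_id = metrics$participant_id),
                            FUN = mean, na.rm = TRUE)
    agg$group <- adaptation$group[match(agg$participant_id,
                                        adaptation$participant_id)]
    agg
  }
  comp_row <- function(name, young_vals, older_vals) {
    if (sum(!is.na(young_vals)) < 3L || sum(!is.na(older_vals)) < 3L) {
      warning("variable '", name, "': fewer than 3 observations per group; ",
              "comparison skipped", call. = FALSE)
      return(NULL)
    }
    gc <- suppressWarnings(compare_groups(older_vals, young_vals,
                                          alpha = cfg$alpha, variable = name))
    data.frame(variable = name, test_used = gc$test_used,
               statistic = gc$statistic, p = gc$p,
               effect_size = gc$effect_size, effect_type = gc$effect_type,
               n_young = sum(!is.na(young_vals)),
               n_older = sum(!is.na(older_vals)),
               mean_young = mean(young_vals, na.rm = TRUE),
               mean_older = mean(older_vals, na.rm = TRUE),
               sd_young = stats::sd(young_vals, na.rm = TRUE),
               sd_older = stats::sd(older_vals, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }
  comparisons <- list()
  basic <- c(mean_walking_speed = "walking_speed",
             mean_trajectory_efficiency = "trajectory_efficiency",
             mean_goal_fixations = "goal_fixation_proportion")
  for (nm in names(basic)) {
    if (!basic[[nm]] %in% names(metrics)) next
    agg <- pmean(basic[[nm]])
    comparisons[[nm]] <- comp_row(nm, agg$x[agg$group == "young"],
                                  agg$x[agg$group == "older"])
  }
  dep <- c(change_ws = "change_ws", ai_ws = "ai_ws", ai_te = "ai_te",
           ai_gf = "ai_gf")
  for (nm in names(dep)) {
    vals <- adaptation[[dep[[nm]]]]
    if (all(is.na(vals))) next
    comparisons[[nm]] <- comp_row(nm, vals[adaptation$group == "young"],
                                  vals[adaptation$group == "older"])
  }
  comparisons <- do.call(rbind, comparisons)
  rownames(comparisons) <- NULL

  cors <- list()
  fam <- 2L
  for (other in c("ai_te", "ai_gf")) {
    if (all(is.na(adaptation[[other]]))) next
    cr <- suppressWarnings(correlate(adaptation$ai_ws, adaptation[[other]],
                                     method = correlation_method,
                                     alpha = cfg$alpha, family_size = fam,
                                     pair = paste0("ai_ws~", other)))
    cors[[other]] <- data.frame(pair = cr$pair, r = cr$r, p = cr$p, n = cr$n,
                                alpha_corrected = cr$alpha_corrected,
                                method = cr$method, stringsAsFactors = FALSE)
  }
  correlations <- if (length(cors) > 0) do.call(rbind, cors) else
    data.frame(pair = character(0), r = numeric(0), p = numeric(0),
               n = integer(0), alpha_corrected = numeric(0),
               method = character(0))
  rownames(correlations) <- NULL
  list(comparisons = comparisons, correlations = correlations)
}

#' Run the whole pipeline from a config
#'
#' Stages: synthesize (or load) the cohort, compute per-trial metrics,
#' derive per-participant adaptation results, run the statistical layer, and
#' write `metrics.csv`, `adaptation.csv`, `stats.json` and `manifest.json`
#' (config snapshot, seed, row counts, captured warnings, output digests)
#' into the output directory. Re-running with the same config reproduces the
#' outputs bit-identically.
#'
#' @param config path to a YAML config file, or an equivalent named list.
#'   Recognized sections: `seed`, `output_dir`, `environment` (path to an
#'   environment file, or omitted for the default room), `cohort`
#'   (`n_per_group`, `n_trials`, `n_extra_older`, `include_gaze`,
#'   `coupling_rho`, optional `young`/`older` template overrides), `analysis`
#'   (overrides for [analysis_config()]), `stats`
#'   (`correlation_method`).
#' @param output_dir overrides the config's output directory.
#' @return invisibly, a list with `metrics`, `adaptation`, `stats`,
#'   `manifest`, and the output paths.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg_in <- if (is.character(config)) {
    if (!file.exists(config)) stop_nav("config file not found: ", config)
    yaml::read_yaml(config)
  } else config
  out_dir <- output_dir %||% cfg_in$output_dir %||% stop_nav("no output_dir configured")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg_in$seed %||% 1L)
  warn_log <- character(0)
  grab <- function(stage, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop_nav("stage '", stage, "' failed: ", conditionMessage(e))),
      warning = function(w) {
        warn_log <<- c(warn_log, paste0(stage, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }
  env <- grab("environment", {
    if (!is.null(cfg_in$environment)) load_environment(cfg_in$environment)
    else environment_model()
  })
  acfg <- grab("config", do.call(analysis_config, cfg_in$analysis %||% list()))
  co <- cfg_in$cohort %||% list()
  n_trials <- as.integer(co$n_trials %||% 8L)
  tpl_args <- function(g) c(list(group = g, n_trials = n_trials),
                            co[[g]] %||% list())
  sim <- grab("cohort+metrics", simulate_cohort_metrics(
    env, n_per_group = as.integer(co$n_per_group %||% 14L),
    n_trials = n_trials, seed = seed,
    young = do.call(group_template, tpl_args("young")),
    older = do.call(group_template, tpl_args("older")),
    gaze = co$include_gaze %||% TRUE,
    n_extra_older = as.integer(co$n_extra_older %||% 2L),
    coupling_rho = co$coupling_rho, cfg = acfg))
  metrics <- sim$metrics
  adaptation <- grab("adaptation", adaptation_results(metrics, cfg = acfg))
  st <- cfg_in$stats %||% list()
  stats_out <- grab("stats", cohort_statistics(
    metrics, adaptation, cfg = acfg,
    correlation_method = st$correlation_method %||% "pearson"))

  paths <- list(metrics = file.path(out_dir, "metrics.csv"),
                adaptation = file.path(out_dir, "adaptation.csv"),
                stats = file.path(out_dir, "stats.json"),
                manifest = file.path(out_dir, "manifest.json"))
  utils::write.csv(metrics, paths$metrics, row.names = FALSE)
  utils::write.csv(adaptation, paths$adaptation, row.names = FALSE)
  jsonlite::write_json(stats_out, paths$stats, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null")
  manifest <- list(
    package_version = as.character(utils::packageVersion("navpace")),
    seed = seed, config = cfg_in,
    rows = list(metrics = nrow(metrics), adaptation = nrow(adaptation),
                comparisons = nrow(stats_out$comparisons),
                correlations = nrow(stats_out$correlations)),
    warnings = warn_log,
    digests = as.list(tools::md5sum(unlist(paths[1:3]))))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(list(metrics = metrics, adaptation = adaptation,
                 stats = stats_out, manifest = manifest, paths = paths))
}
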