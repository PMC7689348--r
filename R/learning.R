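# Spatial-learning metrics and dependent variables: trajectory efficiency,
# the criterion trial, control-profile multipliers, adaptation indices, and
# the percent change in walking speed.

#' Trajectory efficiency
#'
#' Ratio of the shortest (straight-line) distance from the starting position
#' to the center of the goal zone over the total length of the walked
#' trajectory. Values above 1 are possible (the walked path stops at the
#' goal-zone border, short of its center) and are reported as-is.
#'
#' @param path n x 2 polyline of horizontal body-reference positions.
#' @param start 2D starting position, m.
#' @param goal_center 2D goal-zone center, m.
#' @return dimensionless efficiency (> 0, not clamped).
#' @export
trajectory_efficiency <- function(path, start, goal_center) {
  path <- as.matrix(path)
  if (nrow(path) < 2L) stop_nav("path must contain at least two points")
  len <- sum(sqrt(rowSums((path[-1L, , drop = FALSE] -
                             path[-nrow(path), , drop = FALSE])^2)))
  if (len <= 0) stop_nav("zero-length path")
  sqrt(sum((goal_center - start)^2)) / len
}

#' Criterion trial
#'
#' The first trial whose trajectory efficiency strictly exceeds the
#' criterion, provided the following trial also exceeds it. If no trial pair
#' qualifies, the last trial is returned with a warning (fallback).
#'
#' @param te per-trial trajectory efficiencies (length >= 2; `NA` allowed and
#'   treated as not exceeding).
#' @param criterion efficiency criterion (default 0.85).
#' @return 1-based criterion trial index.
#' @export
criterion_trial <- function(te, criterion = 0.85) {
  if (length(te) < 2L) stop_nav("need at least two trials")
  above <- !is.na(te) & te > criterion
  hit <- which(above[-length(te)] & above[-1L])
  if (length(hit) > 0) return(hit[1])
  warning(warningCondition(
    "learning criterion never met on two consecutive trials; using last trial",
    class = "navpace_criterion_fallback"))
  length(te)
}

#' Control profile from the young group
#'
#' Arithmetic mean of the young participants' per-trial metric values,
#' skipping missing values.
#'
#' @param young_metrics participants x trials matrix (or data frame) of one
#'   metric for the control (young) group.
#' @return numeric vector `C` of per-trial means.
#' @export
control_profile <- function(young_metrics) {
  m <- as.matrix(young_metrics)
  C <- colMeans(m, na.rm = TRUE)
  if (any(!is.finite(C))) {
    stop_nav("control profile undefined at trial(s) ",
             paste(which(!is.finite(C)), collapse = ", "),
             ": no young-group data")
  }
  as.numeric(C)
}

#' Adaptation-index multipliers
#'
#' `M_i = C_1 / C_i`, with the first multiplier set to zero (participants are
#' naive on trial 1).
#'
#' @param C control profile from [control_profile()].
#' @return multiplier vector `M` of the same length.
#' @export
multipliers <- function(C) {
  if (any(C == 0)) stop_nav("control profile contains zeros; multipliers undefined")
  M <- C[1] / C
  M[1] <- 0
  M
}

#' Adaptation index
#'
#' `sum_{i=1..n} M_i * S_i` over the trials from the start to the criterion
#' trial `n`. Quantifies the speed of trial-to-trial behavioral change.
#'
#' @param S per-trial values of the metric for one participant.
#' @param M multipliers from [multipliers()].
#' @param n criterion trial.
#' @return the adaptation index.
#' @export
adaptation_index <- function(S, M, n) {
  if (n < 1L) stop_nav("criterion trial must be >= 1")
  if (length(S) < n || length(M) < n) {
    stop_nav("S and M must be defined on trials 1..", n)
  }
  s <- S[seq_len(n)]
  if (anyNA(s)) {
    stop_nav("missing metric value before the criterion trial (trial ",
             paste(which(is.na(s)), collapse = ", "), "); no imputation")
  }
  sum(M[seq_len(n)] * s)
}

#' Percent change in walking speed
#'
#' `100 * (ws_ref - ws_first) / ws_ref`: positive values mean the participant
#' walked slower on the first trial than on the (learned-environment)
#' reference trial.
#'
#' @param ws_first walking speed on the first trial, m/s.
#' @param ws_ref reference (last or penultimate) walking speed, m/s.
#' @return percent change.
#' @export
change_in_walking_speed <- function(ws_first, ws_ref) {
  if (!is.finite(ws_ref) || ws_ref <= 0) {
    stop_nav("reference walking speed must be positive")
  }
  100 * (ws_ref - ws_first) / ws_ref
}

#' Select the reference trial for the walking-speed change score
#'
#' The last trial is used when its walking speed is valid (at least
#' `min_eligible_steps` straight-ahead steps after excluding gait initiation
#' and termination). Otherwise the penultimate trial is used, provided its
#' trajectory efficiency exceeds the learning criterion. Otherwise the
#' reference is missing (with a warning).
#'
#' @param ws per-trial walking speeds (may contain `NA`).
#' @param ws_n per-trial counts of eligible straight steps.
#' @param te per-trial trajectory efficiencies.
#' @param cfg an [analysis_config()].
#' @return list with `trial` (index or `NA`) and `ws_ref` (m/s or `NA`).
#' @export
select_reference_trial <- function(ws, ws_n, te, cfg = analysis_config()) {
  T_ <- length(ws)
  if (T_ < 2L) stop_nav("need at least two trials")
  valid <- !is.na(ws) & ws_n >= cfg$min_eligible_steps
  if (valid[T_]) return(list(trial = T_, ws_ref = ws[T_]))
  pen <- T_ - 1L
  if (valid[pen] && !is.na(te[pen]) && te[pen] > cfg$efficiency_criterion) {
    return(list(trial = pen, ws_ref = ws[pen]))
  }
  warning(warningCondition(
    "no valid reference trial (last invalid, penultimate below criterion)",
    class = "navpace_no_reference_trial"))
  list(trial = NA_integer_, ws_ref = NA_real_)
}

#' Per-participant adaptation results for a cohort
#'
#' From a tidy per-trial metrics table, computes for every participant the
#' criterion trial, the adaptation indices of walking speed, trajectory
#' efficiency and goal fixations (multipliers derived from the control
#' group's per-trial means), and the percent change in walking speed between
#' the first and the reference trial.
#'
#' Control profiles are extended to extra trials (participants that received
#' a ninth trial) by carrying the last control value forward. The
#' first-trial walking speed obeys the same validity rule as the reference
#' trial; participants with an invalid first trial get a missing change
#' score.
#'
#' @param metrics data frame with columns `participant_id`, `group`,
#'   `trial_index`, `walking_speed`, `ws_n_steps`, `trajectory_efficiency`,
#'   `goal_fixation_proportion` (column may be absent for kinematics-only
#'   runs).
#' @param control_group group whose means define the control profile.
#' @param cfg an [analysis_config()].
#' @return data frame with one row per participant: `participant_id`,
#'   `group`, `criterion_trial`, `criterion_fallback`, `ai_ws`, `ai_te`,
#'   `ai_gf`, `change_ws`, `reference_trial`.
#' @export
adaptation_results <- function(metrics, control_group = "young",
                               cfg = analysis_config()) {
  needed <- c("participant_id", "group", "trial_index", "walking_speed",
              "ws_n_steps", "trajectory_efficiency")
  missing_cols <- setdiff(needed, names(metrics))
  if (length(missing_cols) > 0) {
    stop_nav("metrics table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  has_gf <- "goal_fixation_proportion" %in% names(metrics) &&
    any(!is.na(metrics$goal_fixation_proportion))
  pids <- unique(metrics$participant_id)
  n_trials_max <- max(metrics$trial_index)

  wide <- function(col) {
    m <- matrix(NA_real_, length(pids), n_trials_max,
                dimnames = list(pids, NULL))
    m[cbind(match(metrics$participant_id, pids), metrics$trial_index)] <-
      metrics[[col]]
    m
  }
  ws <- wide("walking_speed")
  ws_n <- wide("ws_n_steps")
  te <- wide("trajectory_efficiency")
  gf <- if (has_gf) wide("goal_fixation_proportion") else NULL
  groups <- metrics$group[match(pids, metrics$participant_id)]
  ctrl <- pids[groups == control_group]
  if (length(ctrl) == 0L) stop_nav("no participants in control group '",
                                   control_group, "'")
  ctrl_trials <- sort(unique(metrics$trial_index[
    metrics$participant_id %in% ctrl]))
  mk_M <- function(mat) {
    C <- control_profile(mat[ctrl, ctrl_trials, drop = FALSE])
    if (length(C) < n_trials_max) {     # carry last control value forward
      C <- c(C, rep(C[length(C)], n_trials_max - length(C)))
    }
    multipliers(C)
  }
  M_ws <- mk_M(ws); M_te <- mk_M(te)
  M_gf <- if (has_gf) mk_M(gf) else NULL

  out <- data.frame(participant_id = pids, group = groups,
                    criterion_trial = NA_integer_, criterion_fallback = FALSE,
                    ai_ws = NA_real_, ai_te = NA_real_, ai_gf = NA_real_,
                    change_ws = NA_real_, reference_trial = NA_integer_,
                    stringsAsFactors = FALSE)
  ai_or_na <- function(S, M, n, what, pid) {
    tryCatch(adaptation_index(S, M, n), error = function(e) {
      warning("participant ", pid, ": ", what, " adaptation index undefined (",
              conditionMessage(e), ")", call. = FALSE)
      NA_real_
    })
  }
  for (r in seq_along(pids)) {
    p_trials <- which(!is.na(te[r, ]) | !is.na(ws[r, ]))
    T_p <- max(p_trials)
    fell_back <- FALSE
    n_c <- withCallingHandlers(
      criterion_trial(te[r, seq_len(T_p)], cfg$efficiency_criterion),
      navpace_criterion_fallback = function(w) {
        fell_back <<- TRUE
        invokeRestart("muffleWarning")
      })
    out$criterion_trial[r] <- n_c
    out$criterion_fallback[r] <- fell_back
    out$ai_ws[r] <- ai_or_na(ws[r, ], M_ws, n_c, "walking-speed", pids[r])
    out$ai_te[r] <- ai_or_na(te[r, ], M_te, n_c, "trajectory-efficiency", pids[r])
    if (has_gf) {
      out$ai_gf[r] <- ai_or_na(gf[r, ], M_gf, n_c, "goal-fixation", pids[r])
    }
    ref <- withCallingHandlers(
      select_reference_trial(ws[r, seq_len(T_p)], ws_n[r, seq_len(T_p)],
                             te[r, seq_len(T_p)], cfg),
      navpace_no_reference_trial = function(w) invokeRestart("muffleWarning"))
    out$reference_trial[r] <- ref$trial
    first_valid <- !is.na(ws[r, 1]) && ws_n[r, 1] >= cfg$min_eligible_steps
    if (!is.na(ref$trial) && first_valid) {
      out$change_ws[r] <- change_in_walking_speed(ws[r, 1], ref$ws_ref)
    }
  }
  out
}
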