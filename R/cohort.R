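# Cohort-level synthesis: per-group parameter distributions, reproducible
# per-participant/per-trial random substreams, and ground-truth bookkeeping.
#
# Defaults encode the study conditions the pipeline targets: 14 participants
# per age group, 8 learning trials (a 9th for two older participants), trial
# directness rising along a saturating-exponential learning curve past the
# 0.85 efficiency criterion, goal-fixation probability rising with learning,
# and a trial-1 walking-speed reduction in the older group (mean 20%,
# between-participant SD 25 percentage points, i.e. a between-group effect
# of d = 0.8 on the change score).

#' Per-group distribution template for the synthetic cohort
#'
#' @param group `"young"` or `"older"`.
#' @param n_trials number of learning trials programmed per participant.
#' @param ... named overrides of any template field (e.g. `slowdown_mean`).
#' @return a named list of distribution parameters (class `group_template`).
#' @export
group_template <- function(group = c("young", "older"), n_trials = 8L, ...) {
  group <- match.arg(group)
  tpl <- if (group == "young") {
    list(speed_mean = 1.30, speed_sd = 0.12,
         slowdown_mean = 0, slowdown_sd = 25,
         speed_trial_jitter = 0.03,
         d1_mean = 0.55, d1_sd = 0.05,
         dmax_mean = 0.95, dmax_sd = 0.015, dmax_min = 0.90,
         tau_te = 1.2, te_trial_jitter = 0.02,
         p1 = 0.15, pmax_mean = 0.45, pmax_sd = 0.05, tau_gf = 1.5,
         step_freq_mean = 1.90, step_freq_sd = 0.10,
         orientation_mean = 1.5, orientation_sd = 0.3)
  } else {
    list(speed_mean = 1.05, speed_sd = 0.12,
         slowdown_mean = 20, slowdown_sd = 25,
         speed_trial_jitter = 0.03,
         d1_mean = 0.45, d1_sd = 0.05,
         dmax_mean = 0.92, dmax_sd = 0.02, dmax_min = 0.88,
         tau_te = 2.0, te_trial_jitter = 0.02,
         p1 = 0.12, pmax_mean = 0.35, pmax_sd = 0.05, tau_gf = 2.5,
         step_freq_mean = 1.75, step_freq_sd = 0.10,
         orientation_mean = 2.2, orientation_sd = 0.4)
  }
  common <- list(group = group, n_trials = as.integer(n_trials),
                 noise_pos = 0.001, noise_dir = 0.003, step_height = 0.05,
                 fixation_median = 0.30, fixation_sigma = 0.4,
                 # coupled-mode fields (used when coupling_rho is set):
                 # per-participant walking-speed and trajectory-efficiency
                 # modulation amplitudes drawn from a bivariate normal; the
                 # cruise speed is common to both groups so that the pooled
                 # adaptation-index correlation reflects the coupling alone
                 coupled_speed = 1.20,
                 ws_amp_mean = 0.30, ws_amp_sd = 0.10,
                 ws_recovery = c(1, 0.75, 0.5, 0.3, 0.15, 0.07, 0.03, 0),
                 # steep recovery after trial 2 keeps the criterion trial at
                 # 3 for the whole amplitude range, so the pooled adaptation
                 # indices share no criterion-trial mixture
                 te_amp_mean = 0.30, te_amp_sd = 0.05,
                 te_shape = c(1, 0.95, 0.15, 0.06, 0.02, 0.01, 0.005, 0),
                 te_max = 0.96)
  tpl <- c(tpl, common)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(tpl))
  if (length(unknown) > 0) stop_nav("unknown template field(s): ",
                                    paste(unknown, collapse = ", "))
  tpl[names(dots)] <- dots
  class(tpl) <- "group_template"
  tpl
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Draw one participant's navigator parameters from a template.
# Consumes a fixed amount of the current RNG stream regardless of which
# trials are later generated, so trial subsets stay reproducible.
draw_participant_params <- function(tpl, n_trials = tpl$n_trials,
                                    coupling_rho = NULL) {
  ii <- seq_len(n_trials) - 1L
  if (is.null(coupling_rho)) {
    v <- stats::rnorm(1, tpl$speed_mean, tpl$speed_sd)
    slow <- clamp(stats::rnorm(1, tpl$slowdown_mean, tpl$slowdown_sd), -75, 75)
    speeds <- v + stats::rnorm(n_trials, 0, tpl$speed_trial_jitter)
    speeds[1] <- v * (1 - slow / 100) +
      stats::rnorm(1, 0, tpl$speed_trial_jitter)
    speeds <- clamp(speeds, 0.3, 2.2)
    d1 <- stats::rnorm(1, tpl$d1_mean, tpl$d1_sd)
    dmax <- clamp(stats::rnorm(1, tpl$dmax_mean, tpl$dmax_sd),
                  tpl$dmax_min, 0.975)
    dct <- dmax - (dmax - d1) * exp(-ii / tpl$tau_te) +
      stats::rnorm(n_trials, 0, tpl$te_trial_jitter)
    dct <- clamp(dct, 0.35, 0.975)
  } else {
    z1 <- stats::rnorm(1)
    z2 <- coupling_rho * z1 + sqrt(1 - coupling_rho^2) * stats::rnorm(1)
    a_ws <- clamp(tpl$ws_amp_mean + tpl$ws_amp_sd * z1, 0, 0.8)
    a_te <- clamp(tpl$te_amp_mean + tpl$te_amp_sd * z2, 0.15, 0.45)
    rec <- c(tpl$ws_recovery, rep(0, n_trials))[seq_len(n_trials)]
    shp <- c(tpl$te_shape, rep(0, n_trials))[seq_len(n_trials)]
    speeds <- clamp(tpl$coupled_speed - a_ws * rec +
                      stats::rnorm(n_trials, 0, 0.02), 0.3, 2.2)
    dct <- clamp(tpl$te_max - a_te * shp +
                   stats::rnorm(n_trials, 0, 0.008), 0.35, 0.975)
  }
  pmax_ <- clamp(stats::rnorm(1, tpl$pmax_mean, tpl$pmax_sd), 0.05, 0.9)
  pgf <- clamp(pmax_ - (pmax_ - tpl$p1) * exp(-ii / tpl$tau_gf), 0.02, 0.9)
  f_step <- clamp(stats::rnorm(1, tpl$step_freq_mean, tpl$step_freq_sd),
                  1.2, 2.6)
  orient <- clamp(stats::rnorm(1, tpl$orientation_mean, tpl$orientation_sd),
                  0.9, 4)
  start_offset <- sample.int(4L, 1) - 1L
  navigator_params(speeds = speeds, directness = dct, goal_fix_prob = pgf,
                   step_frequency = f_step, step_height = tpl$step_height,
                   fixation_median = tpl$fixation_median,
                   fixation_sigma = tpl$fixation_sigma,
                   noise_pos = tpl$noise_pos, noise_dir = tpl$noise_dir,
                   orientation_duration = orient,
                   start_offset = start_offset)
}

# Per-participant parameter draws for a whole cohort (deterministic in seed).
draw_cohort_params <- function(seed, n_per_group = 14L, n_trials = 8L,
                               young = group_template("young", n_trials),
                               older = group_template("older", n_trials),
                               n_extra_older = 2L, coupling_rho = NULL) {
  stopifnot(n_per_group >= 2L)
  n_trials <- as.integer(n_trials)
  out <- list()
  tpls <- list(young = young, older = older)
  for (gi in 1:2) {
    gname <- names(tpls)[gi]
    for (pi in seq_len(n_per_group)) {
      nt <- n_trials + if (gname == "older" && pi <= n_extra_older) 1L else 0L
      params <- with_seed(derive_seed(seed, gi, pi, 0L),
                          draw_participant_params(tpls[[gi]], nt, coupling_rho))
      out[[length(out) + 1L]] <- list(
        participant_id = sprintf("%s%02d", toupper(substr(gname, 1, 1)), pi),
        group = gname, group_index = gi, p_index = pi,
        n_trials = nt, params = params)
    }
  }
  out
}

#' Generate a synthetic cohort
#'
#' Draws per-participant navigator parameters from the two group templates
#' (fresh random substream per participant, and per trial), then generates
#' every requested trial with ground truth. With identical arguments the
#' cohort is bit-identical.
#'
#' @param env a `nav_environment`.
#' @param n_per_group participants per age group (>= 2).
#' @param n_trials learning trials per participant.
#' @param seed base seed for all substreams.
#' @param young,older group templates from [group_template()].
#' @param trials optional integer vector: generate only these trial indices
#'   (e.g. `c(1, 7, 8)`); parameter draws are unaffected.
#' @param include_gaze generate gaze streams.
#' @param n_extra_older number of older participants receiving one extra
#'   trial (the study added a ninth trial for two of them).
#' @param coupling_rho optional correlation at which the per-participant
#'   walking-speed and directness modulation amplitudes are coupled; enables
#'   the coupled generator mode (see the methods vignette).
#' @return object of class `nav_cohort`: list with `participants` (each with
#'   `params` and a `trials` list of `generate_trial()` results), `env`,
#'   `seed`.
#' @export
generate_cohort <- function(env, n_per_group = 14L, n_trials = 8L, seed = 1L,
                            young = group_template("young", n_trials),
                            older = group_template("older", n_trials),
                            trials = NULL, include_gaze = TRUE,
                            n_extra_older = 2L, coupling_rho = NULL) {
  specs <- draw_cohort_params(seed, n_per_group, n_trials, young, older,
                              n_extra_older, coupling_rho)
  participants <- lapply(specs, function(sp) {
    idx <- seq_len(sp$n_trials)
    if (!is.null(trials)) idx <- intersect(trials, idx)
    sp$trials <- lapply(idx, function(ti) {
      generate_trial(env, sp$params, ti,
                     seed = derive_seed(seed, sp$group_index, sp$p_index, ti),
                     include_gaze = include_gaze,
                     participant_id = sp$participant_id, group = sp$group)
    })
    names(sp$trials) <- as.character(idx)
    sp
  })
  structure(list(participants = participants, env = env, seed = seed),
            class = "nav_cohort")
}

#' @export
print.nav_cohort <- function(x, ...) {
  nt <- sum(vapply(x$participants, function(p) length(p$trials), integer(1)))
  cat("<nav_cohort> ", length(x$participants), " participants, ", nt,
      " trials (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Ground-truth per-trial metrics of a cohort
#'
#' @param cohort a `nav_cohort`.
#' @return data frame with one row per generated trial: programmed speed,
#'   efficiency (directness), goal-fixation probability, the realized true
#'   goal-fixation proportion, and the programmed percent change in walking
#'   speed (first vs. last programmed trial speed) repeated per participant.
#' @export
cohort_truth_metrics <- function(cohort) {
  rows <- lapply(cohort$participants, function(p) {
    sp <- p$params$speeds
    change_true <- 100 * (sp[length(sp)] - sp[1]) / sp[length(sp)]
    do.call(rbind, lapply(names(p$trials), function(ti) {
      tr <- p$trials[[ti]]$truth
      data.frame(participant_id = p$participant_id, group = p$group,
                 trial_index = as.integer(ti), true_speed = tr$speed,
                 true_efficiency = tr$efficiency,
                 goal_fix_prob = tr$goal_fix_prob,
                 true_goal_fix_proportion = tr$goal_fix_proportion,
                 true_change_ws = change_true,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
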