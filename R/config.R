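# Analysis configuration: every tuning constant of the pipeline, named and
# defaulted, so the whole processing chain can be perturbed from one place.

#' Analysis configuration
#'
#' @param filter_cutoff low-pass cutoff for marker kinematics, Hz.
#' @param filter_order Butterworth order (applied zero-phase).
#' @param straight_threshold maximum absolute heading change (degrees) for a
#'   step to count as straight-ahead; the comparison is strict (`< threshold`).
#' @param min_fixation minimum fixation duration, ms; shorter candidate
#'   fixations are discarded.
#' @param dispersion_k multiplier on the inter-quartile range in the
#'   dispersion threshold `median + dispersion_k * IQR`.
#' @param efficiency_criterion trajectory-efficiency level that must be
#'   exceeded on two consecutive trials to define the criterion trial.
#' @param target_rate common rate gaze is resampled to, Hz.
#' @param standing_speed_threshold horizontal speed below which the body is
#'   considered standing, m/s.
#' @param standing_min_duration minimum duration of a standing period, s.
#' @param strike_refractory per-foot refractory period between heel strikes, s.
#' @param strike_min_downswing minimum peak downward heel velocity preceding a
#'   strike, m/s.
#' @param max_gaze_gap gaze gaps longer than this (s) are flagged invalid
#'   rather than interpolated.
#' @param min_eligible_steps straight-ahead steps (after dropping the trial's
#'   first and last overall steps) required for a trial's walking speed to be
#'   considered valid.
#' @param fixations_navigation_only restrict fixation counting to the
#'   navigation phase (default counts the whole trial).
#' @param alpha significance level for the statistical layer.
#' @return an object of class `nav_config` (a named list).
#' @export
analysis_config <- function(filter_cutoff = 10, filter_order = 2,
                            straight_threshold = 45, min_fixation = 100,
                            dispersion_k = 2, efficiency_criterion = 0.85,
                            target_rate = 120,
                            standing_speed_threshold = 0.1,
                            standing_min_duration = 0.5,
                            strike_refractory = 0.3,
                            strike_min_downswing = 0.005,
                            max_gaze_gap = 0.2,
                            min_eligible_steps = 2L,
                            fixations_navigation_only = FALSE,
                            alpha = 0.05) {
  cfg <- list(filter_cutoff = filter_cutoff, filter_order = filter_order,
              straight_threshold = straight_threshold,
              min_fixation = min_fixation, dispersion_k = dispersion_k,
              efficiency_criterion = efficiency_criterion,
              target_rate = target_rate,
              standing_speed_threshold = standing_speed_threshold,
              standing_min_duration = standing_min_duration,
              strike_refractory = strike_refractory,
              strike_min_downswing = strike_min_downswing,
              max_gaze_gap = max_gaze_gap,
              min_eligible_steps = as.integer(min_eligible_steps),
              fixations_navigation_only = isTRUE(fixations_navigation_only),
              alpha = alpha)
  num <- cfg[!names(cfg) %in% "fixations_navigation_only"]
  bad <- names(num)[!vapply(num, function(x) is.numeric(x) && length(x) == 1L && x > 0,
                            logical(1))]
  if (length(bad) > 0) stop_nav("config values must be strictly positive scalars: ",
                                paste(bad, collapse = ", "))
  if (cfg$efficiency_criterion >= 1) stop_nav("efficiency_criterion must lie in (0, 1)")
  if (cfg$alpha >= 1) stop_nav("alpha must lie in (0, 1)")
  class(cfg) <- "nav_config"
  cfg
}
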