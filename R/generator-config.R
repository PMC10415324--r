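#' Configuration for the synthetic session generator
#'
#' Bundles the paradigm geometry, trial counts and noise levels used by
#' [simulate_session()] and [simulate_cohort()]. Defaults reproduce the
#' double-step adaptation paradigm: fixation 6.5 degrees left of screen
#' center, saccade target 6.5 degrees right (13 degree saccades), a 3 degree
#' intra-saccadic target displacement triggered when eye velocity crosses
#' 30 deg/s, 1 kHz sampling, 20 baseline trials, 80 adaptation trials and 20
#' de-adaptation trials, each saccade trial followed by a localization trial.
#'
#' @param sampling_rate gaze sampling rate in Hz.
#' @param fixation_x horizontal fixation-point position, degrees
#'   (screen-centered, rightward positive).
#' @param target_x horizontal position of the initial saccade target (T1),
#'   degrees.
#' @param displacement intra-saccadic displacement magnitude in degrees;
#'   applied with positive sign (outward) or negative sign (inward) by the
#'   session simulator.
#' @param n_saccade_trials number of saccade trials up to the end of the
#'   adaptation phase (baseline included, de-adaptation excluded).
#' @param n_baseline number of baseline trials (no displacement) at session
#'   start.
#' @param n_deadapt number of de-adaptation trials (no displacement) appended
#'   at session end.
#' @param display_latency_ms mean latency of the target displacement after
#'   the detected saccade onset (the 30 deg/s crossing), ms.
#' @param display_latency_jitter_ms half-width of the uniform jitter around
#'   `display_latency_ms`, ms.
#' @param motor_noise_sd trial-to-trial standard deviation of saccade
#'   amplitude, degrees.
#' @param loc_noise_sd standard deviation of localization (mouse click)
#'   noise, degrees.
#' @param fix_scatter named numeric vector `c(sigma_h=, sigma_v=, rho=)`
#'   describing the bivariate-Gaussian trial-to-trial scatter of fixation,
#'   degrees and unitless correlation.
#' @param saccade_d0_ms,saccade_d1_ms_per_deg intercept and slope of the
#'   main-sequence duration law `D = d0 + d1 * amplitude` (ms); the defaults
#'   give about 42 ms for a 13 degree saccade.
#' @param saccade_latency_ms,saccade_latency_sd_ms mean and SD of saccade
#'   latency after fixation-point offset, ms.
#' @param fixation_dur_ms fixation period before fixation-point offset, ms.
#' @param trace_tail_ms post-saccadic trace duration, ms.
#' @param loc_trace_ms trace duration of a localization trial, ms.
#' @param flash_dur_ms duration of the localization flash, ms.
#' @param seed integer seed controlling all randomness of the generator.
#' @return an object of class `generator_config` (a validated list).
#' @export
#' @examples
#' cfg <- generator_config(seed = 42)
#' cfg$target_x - cfg$fixation_x  # the 13 degree saccade vector
generator_config <- function(sampling_rate = 1000,
                             fixation_x = -6.5,
                             target_x = 6.5,
                             displacement = 3,
                             n_saccade_trials = 100,
                             n_baseline = 20,
                             n_deadapt = 20,
                             display_latency_ms = 22,
                             display_latency_jitter_ms = 2,
                             motor_noise_sd = 0.3,
                             loc_noise_sd = 0.3,
                             fix_scatter = c(sigma_h = 0.3, sigma_v = 0.3, rho = 0.1),
                             saccade_d0_ms = 20,
                             saccade_d1_ms_per_deg = 1.7,
                             saccade_latency_ms = 180,
                             saccade_latency_sd_ms = 30,
                             fixation_dur_ms = 100,
                             trace_tail_ms = 100,
                             loc_trace_ms = 400,
                             flash_dur_ms = 24,
                             seed = 1L) {
  cfg <- list(
    sampling_rate = sampling_rate, fixation_x = fixation_x,
    target_x = target_x, displacement = displacement,
    n_saccade_trials = n_saccade_trials, n_baseline = n_baseline,
    n_deadapt = n_deadapt,
    display_latency_ms = display_latency_ms,
    display_latency_jitter_ms = display_latency_jitter_ms,
    motor_noise_sd = motor_noise_sd, loc_noise_sd = loc_noise_sd,
    fix_scatter = fix_scatter,
    saccade_d0_ms = saccade_d0_ms,
    saccade_d1_ms_per_deg = saccade_d1_ms_per_deg,
    saccade_latency_ms = saccade_latency_ms,
    saccade_latency_sd_ms = saccade_latency_sd_ms,
    fixation_dur_ms = fixation_dur_ms, trace_tail_ms = trace_tail_ms,
    loc_trace_ms = loc_trace_ms, flash_dur_ms = flash_dur_ms,
    seed = as.integer(seed))
  validate_generator_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(cfg$sampling_rate > 0)
  if (cfg$n_baseline + cfg$n_deadapt >= cfg$n_saccade_trials)
    stop("n_baseline + n_deadapt must be smaller than n_saccade_trials")
  if (cfg$n_baseline < 1)
    stop("n_baseline must be at least 1")
  sc <- cfg$fix_scatter
  if (!all(c("sigma_h", "sigma_v", "rho") %in% names(sc)))
    stop("fix_scatter must be a named vector with sigma_h, sigma_v, rho")
  if (abs(sc[["rho"]]) >= 1) stop("|rho| must be < 1")
  if (sc[["sigma_h"]] < 0 || sc[["sigma_v"]] < 0)
    stop("fixation scatter SDs must be non-negative")
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat(sprintf("  geometry : FP %+0.1f deg, T1 %+0.1f deg, displacement %0.1f deg\n",
              x$fixation_x, x$target_x, x$displacement))
  cat(sprintf("  trials   : %d baseline / %d adaptation / %d de-adaptation\n",
              x$n_baseline, x$n_saccade_trials - x$n_baseline, x$n_deadapt))
  cat(sprintf("  sampling : %g Hz, seed %d\n", x$sampling_rate, x$seed))
  invisible(x)
}

#' Ground-truth learning parameters of one simulated participant
#'
#' @param aq_score integer AQ total in 0-50.
#' @param alpha oculomotor learning rate in \[0, 1\]: the fraction of the
#'   post-saccadic error incorporated into the adaptation state each trial.
#' @param lam per-trial retention of the adaptation state, in (0, 1\].
#' @param gamma lag-1 serial coupling: degrees of localization shift per
#'   degree of previous-trial post-saccadic error.
#' @param kappa transfer ratio from the motor adaptation state to
#'   localization under fixation.
#' @param alpha_p learning rate of the separate perceptual map probed by
#'   post-saccadic localization; independent of `alpha`.
#' @return an object of class `participant_profile`.
#' @export
participant_profile <- function(aq_score, alpha, lam = 0.98, gamma = 0,
                                kappa = 0.7, alpha_p = 0.1) {
  aq_score <- as.integer(aq_score)
  if (aq_score < 0 || aq_score > 50) stop("aq_score must lie in 0-50")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (lam <= 0 || lam > 1) stop("lam must lie in (0, 1]")
  structure(list(aq_score = aq_score, alpha = alpha, lam = lam,
                 gamma = gamma, kappa = kappa, alpha_p = alpha_p),
            class = "participant_profile")
}

#' Map an AQ score to learning parameters (default trait mapping)
#'
#' Encodes the generative hypothesis behind the simulated cohorts: in the
#' outward condition the oculomotor learning rate `alpha` and the serial
#' coupling `gamma` decline linearly to zero across the sampled AQ range,
#' while in the inward condition `alpha` is constant. The perceptual
#' learning rate `alpha_p` is trait-independent, so participants whose motor
#' map does not adapt still shift their perceptual reports.
#'
#' @param aq_score AQ total.
#' @param trait_range numeric length-2, the AQ range of the cohort over
#'   which the linear decline is defined.
#' @param condition `"outward"` or `"inward"`.
#' @param alpha_max learning rate at the low end of the trait range.
#' @param gamma_max serial coupling at the low end of the trait range.
#' @inheritParams participant_profile
#' @return a [participant_profile()].
#' @export
profile_from_trait <- function(aq_score, trait_range = c(10, 28),
                               condition = c("outward", "inward"),
                               alpha_max = 0.15, gamma_max = 0.5,
                               lam = 0.98, kappa = 0.7, alpha_p = 0.1) {
  condition <- match.arg(condition)
  f <- (trait_range[2] - aq_score) / (trait_range[2] - trait_range[1])
  f <- min(1, max(0, f))
  alpha <- if (condition == "outward") alpha_max * f else alpha_max
  participant_profile(aq_score, alpha = alpha, lam = lam,
                      gamma = gamma_max * f, kappa = kappa, alpha_p = alpha_p)
}

#' @export
print.participant_profile <- function(x, ...) {
  cat(sprintf(
    "<participant_profile> AQ %d | alpha %.3f lam %.3f gamma %.2f kappa %.2f alpha_p %.2f\n",
    x$aq_score, x$alpha, x$lam, x$gamma, x$kappa, x$alpha_p))
  invisible(x)
}
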