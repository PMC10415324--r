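#' One-trial update of the oculomotor adaptation state
#'
#' Single-state delta rule with retention: the new state is
#' `lam * g + alpha * error`. Under a constant post-saccadic error drive
#' `D - g` (constant displacement `D`, no noise) the state converges to the
#' closed-form asymptote `alpha * D / (1 - lam + alpha)`, see
#' [adaptation_asymptote()].
#'
#' @param g current adaptation state, degrees.
#' @param error post-saccadic error of the trial, degrees.
#' @param alpha learning rate.
#' @param lam retention factor.
#' @return updated state, degrees.
#' @export
#' @examples
#' update_adaptation_state(0, 3, alpha = 0.15, lam = 1)  # 0.45
update_adaptation_state <- function(g, error, alpha, lam) {
  if (!all(is.finite(c(g, error, alpha, lam))))
    stop("update_adaptation_state requires finite inputs")
  lam * g + alpha * error
}

#' Fixed point of the adaptation state under a constant displacement
#'
#' @param displacement constant target displacement `D`, degrees.
#' @inheritParams update_adaptation_state
#' @return the asymptotic state `alpha * D / (1 - lam + alpha)`, degrees.
#' @export
adaptation_asymptote <- function(displacement, alpha, lam) {
  alpha * displacement / (1 - lam + alpha)
}

#' Main-sequence saccade duration
#'
#' Linear duration law `D = d0 + d1 * amplitude` in ms.
#'
#' @param amplitude saccade amplitude, degrees.
#' @param config a [generator_config()].
#' @return duration, ms.
#' @export
saccade_duration_ms <- function(amplitude, config = generator_config()) {
  config$saccade_d0_ms + config$saccade_d1_ms_per_deg * amplitude
}

#' Analytic kinematics of the raised-sine saccade profile
#'
#' The generator moves the eye with a raised-sine velocity profile
#' `v(t) = (pi * A / (2 * D)) * sin(pi * t / D)` for `t` in `[0, D]`
#' (amplitude `A` deg, duration `D` s), which integrates exactly to `A` and
#' has closed-form threshold crossings. `saccade_peak_velocity()` returns
#' `pi * A / (2 * D)` in deg/s; `saccade_threshold_crossing()` returns the
#' times (s, relative to movement start) at which velocity rises above and
#' falls below `threshold`.
#'
#' @inheritParams saccade_duration_ms
#' @param threshold velocity threshold, deg/s.
#' @return peak velocity (deg/s), or a named vector `c(up=, down=)` of
#'   crossing times in seconds.
#' @export
saccade_peak_velocity <- function(amplitude, config = generator_config()) {
  d <- saccade_duration_ms(amplitude, config) / 1000
  pi * amplitude / (2 * d)
}

#' @rdname saccade_peak_velocity
#' @export
saccade_threshold_crossing <- function(amplitude, config = generator_config(),
                                       threshold = 30) {
  d <- saccade_duration_ms(amplitude, config) / 1000
  peak <- pi * amplitude / (2 * d)
  if (threshold >= peak)
    stop("threshold exceeds the peak velocity of this saccade")
  up <- (d / pi) * asin(threshold * d * 2 / (pi * amplitude))
  c(up = up, down = d - up)
}

#' Position time course of a raised-sine saccade
#'
#' Piecewise position (deg, relative to the pre-saccadic position) of a
#' saccade starting at `onset_ms` with the raised-sine velocity profile:
#' 0 before onset, `(A/2) * (1 - cos(pi * t / D))` during the movement,
#' `A` afterwards. Useful for composing custom traces in tests.
#'
#' @param t_ms sample times, ms.
#' @param onset_ms movement start, ms.
#' @param amplitude amplitude `A`, deg.
#' @param dur_ms duration `D`, ms.
#' @return numeric vector of positions.
#' @export
raised_sine_position <- function(t_ms, onset_ms, amplitude, dur_ms) {
  u <- (t_ms - onset_ms) / dur_ms
  x <- numeric(length(t_ms))
  mid <- u > 0 & u < 1
  x[mid] <- (amplitude / 2) * (1 - cos(pi * u[mid]))
  x[u >= 1] <- amplitude
  x
}

#' Simulate the gaze trace of a single saccade
#'
#' Produces a sampled trace holding fixation at `fixation_x`, executing a
#' raised-sine saccade of the requested amplitude starting at `onset_ms`,
#' then holding the landing position.
#'
#' @param amplitude saccade amplitude, degrees (> 0 required; use a negative
#'   `direction` via `amplitude` sign handled by the caller).
#' @param onset_ms movement start time within the trace, ms.
#' @param config a [generator_config()] (sampling rate and duration law).
#' @param fixation_x starting horizontal position, degrees.
#' @param total_ms trace duration; defaults to onset + duration + tail.
#' @return a data.frame with columns `t_ms`, `x_deg`, `y_deg`,
#'   `pupil_valid`.
#' @export
simulate_saccade_trace <- function(amplitude, onset_ms,
                                   config = generator_config(),
                                   fixation_x = 0, total_ms = NULL) {
  if (!is.finite(amplitude) || amplitude <= 0)
    stop("amplitude must be positive")
  dur <- saccade_duration_ms(amplitude, config)
  if (is.null(total_ms)) total_ms <- onset_ms + dur + config$trace_tail_ms
  step <- 1000 / config$sampling_rate
  t_ms <- seq(0, total_ms, by = step)
  x <- fixation_x + raised_sine_position(t_ms, onset_ms, amplitude, dur)
  data.frame(t_ms = t_ms, x_deg = x, y_deg = 0,
             pupil_valid = TRUE)
}

#' Sample bivariate-Gaussian fixation scatter
#'
#' @param n_samples number of samples.
#' @param config a [generator_config()]; its `fix_scatter` entry supplies
#'   the SDs and correlation.
#' @param center length-2 numeric, the mean position (deg).
#' @return a data.frame with columns `x`, `y` (deg).
#' @export
simulate_fixation_scatter <- function(n_samples, config = generator_config(),
                                      center = c(0, 0)) {
  sc <- config$fix_scatter
  sh <- sc[["sigma_h"]]; sv <- sc[["sigma_v"]]; rho <- sc[["rho"]]
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  sigma <- matrix(c(sh^2, rho * sh * sv, rho * sh * sv, sv^2), 2, 2)
  xy <- MASS::mvrnorm(n_samples, mu = center, Sigma = sigma)
  xy <- matrix(xy, ncol = 2)
  data.frame(x = xy[, 1], y = xy[, 2])
}

## internal: uniform displacement latency after the detected onset
draw_display_latency <- function(config) {
  runif(1, config$display_latency_ms - config$display_latency_jitter_ms,
        config$display_latency_ms + config$display_latency_jitter_ms)
}

#' Simulate one experimental session
#'
#' Generates the full alternating sequence of saccade and localization
#' trials for one participant in one condition, together with 1 kHz gaze
#' traces and the latent ground truth. Trial structure: `n_baseline`
#' saccade trials without displacement, then adaptation trials with a
#' velocity-contingent +3 (outward) or -3 (inward) degree displacement
#' delivered ~22 ms after the detected onset, then `n_deadapt`
#' de-adaptation trials without displacement; every saccade trial is
#' followed by a localization trial.
#'
#' In `mode = "fixation"` localization reports are made while fixating and
#' couple to the motor state (`kappa`) and to the previous post-saccadic
#' error (`gamma`). In `mode = "post_saccadic"` the participant saccades to
#' the flashed target before reporting, and reports follow a separate
#' perceptual state updated at rate `alpha_p`.
#'
#' @param profile a [participant_profile()].
#' @param config a [generator_config()].
#' @param condition `"outward"` or `"inward"`.
#' @param mode localization mode, `"fixation"` or `"post_saccadic"`.
#' @param seed optional integer overriding `config$seed`.
#' @return an object of class `sim_session`: a list with elements
#'   `trials` (trial table), `gaze` (gaze samples keyed by `trial_id`),
#'   `ground_truth` (per-trial latent state), `profile`, `config`,
#'   `condition`, `mode`.
#' @export
simulate_session <- function(profile, config = generator_config(),
                             condition = c("outward", "inward"),
                             mode = c("fixation", "post_saccadic"),
                             seed = NULL) {
  condition <- match.arg(condition)
  mode <- match.arg(mode)
  if (!inherits(profile, "participant_profile"))
    stop("profile must be a participant_profile")
  set.seed(if (is.null(seed)) config$seed else as.integer(seed))

  n_total <- config$n_saccade_trials + config$n_deadapt
  ecc <- config$target_x - config$fixation_x          # 13 deg
  disp_sign <- if (condition == "outward") 1 else -1
  sc_step <- 1000 / config$sampling_rate

  trials <- vector("list", 2L * n_total)
  gaze <- vector("list", 2L * n_total)
  truth <- vector("list", n_total)

  g <- 0    # motor adaptation state (deg)
  p <- 0    # perceptual map state (deg), exp2 post-saccadic mode
  err <- NA_real_

  for (k in seq_len(n_total)) {
    phase <- if (k <= config$n_baseline) "baseline"
             else if (k <= config$n_saccade_trials) "adaptation"
             else "deadaptation"
    disp <- if (phase == "adaptation") disp_sign * config$displacement else 0

    ## ---- saccade trial -------------------------------------------------
    fp_off <- config$fixation_dur_ms + runif(1)   # decorrelate sample grid
    lat <- max(80, rnorm(1, config$saccade_latency_ms,
                         config$saccade_latency_sd_ms))
    onset <- fp_off + lat
    amp <- ecc + g + rnorm(1, 0, config$motor_noise_sd)
    amp <- max(amp, 1)                            # keep a forward saccade
    dur <- saccade_duration_ms(amp, config)
    cross <- onset + 1000 * saccade_threshold_crossing(amp, config)[["up"]]
    disp_t <- if (phase == "adaptation") cross + draw_display_latency(config)
              else NA_real_
    total <- onset + dur + config$trace_tail_ms
    t_ms <- seq(0, total, by = sc_step)
    x <- config$fixation_x + raised_sine_position(t_ms, onset, amp, dur)
    sacc_id <- 2L * k - 1L
    gaze[[sacc_id]] <- data.frame(trial_id = sacc_id, t_ms = t_ms,
                                  x_deg = x, y_deg = 0, pupil_valid = TRUE)
    t2 <- config$target_x + disp
    landing_ecc <- amp                             # from fixation point
    sacc_err <- (t2 - config$fixation_x) - landing_ecc
    trials[[sacc_id]] <- data.frame(
      trial_id = sacc_id, block = k, trial_type = "saccade",
      condition = condition, phase_true = phase,
      fp_x = config$fixation_x, t1_x = config$target_x, t2_x = t2,
      fp_off_t = fp_off, t1_on_t = fp_off, displacement_t = disp_t,
      flash_on_t = NA_real_, flash_off_t = NA_real_,
      click_x = NA_real_, stringsAsFactors = FALSE)

    g_pre <- g; p_pre <- p
    g <- update_adaptation_state(g, sacc_err, profile$alpha, profile$lam)
    p <- update_adaptation_state(p, sacc_err, profile$alpha_p, profile$lam)
    err <- sacc_err
    truth[[k]] <- data.frame(block = k, phase = phase, g_pre = g_pre,
                             g_post = g, p_pre = p_pre, p_post = p,
                             amplitude = amp, saccade_error = sacc_err)

    ## ---- localization trial --------------------------------------------
    loc_id <- 2L * k
    off <- simulate_fixation_scatter(1, config)
    flash_on <- config$fixation_dur_ms
    flash_off <- flash_on + config$flash_dur_ms
    if (mode == "fixation") {
      t_loc <- seq(0, config$loc_trace_ms, by = sc_step)
      gaze[[loc_id]] <- data.frame(
        trial_id = loc_id, t_ms = t_loc,
        x_deg = config$fixation_x + off$x, y_deg = off$y,
        pupil_valid = TRUE)
      click <- config$fixation_x + ecc + profile$kappa * g +
        profile$gamma * err + rnorm(1, 0, config$loc_noise_sd)
      ttype <- "localization_fixation"
    } else {
      loc_lat <- max(60, rnorm(1, 120, 20))        # saccade after flash off
      loc_onset <- flash_off + loc_lat
      loc_amp <- max(ecc + p + rnorm(1, 0, config$motor_noise_sd), 1)
      loc_dur <- saccade_duration_ms(loc_amp, config)
      total_loc <- loc_onset + loc_dur + config$trace_tail_ms
      t_loc <- seq(0, total_loc, by = sc_step)
      gaze[[loc_id]] <- data.frame(
        trial_id = loc_id, t_ms = t_loc,
        x_deg = config$fixation_x + off$x +
          raised_sine_position(t_loc, loc_onset, loc_amp, loc_dur),
        y_deg = off$y, pupil_valid = TRUE)
      click <- config$fixation_x + ecc + p +
        rnorm(1, 0, config$loc_noise_sd)
      ttype <- "localization_postsaccadic"
    }
    trials[[loc_id]] <- data.frame(
      trial_id = loc_id, block = k, trial_type = ttype,
      condition = condition, phase_true = phase,
      fp_x = config$fixation_x, t1_x = config$target_x, t2_x = NA_real_,
      fp_off_t = flash_on, t1_on_t = NA_real_, displacement_t = NA_real_,
      flash_on_t = flash_on, flash_off_t = flash_off,
      click_x = click, stringsAsFactors = FALSE)
  }

  structure(list(trials = do.call(rbind, trials),
                 gaze = do.call(rbind, gaze),
                 ground_truth = do.call(rbind, truth),
                 profile = profile, config = config,
                 condition = condition, mode = mode),
            class = "sim_session")
}

#' @export
print.sim_session <- function(x, ...) {
  cat(sprintf("<sim_session> %s/%s | AQ %d | %d trials, %d gaze samples\n",
              x$condition, x$mode, x$profile$aq_score,
              nrow(x$trials), nrow(x$gaze)))
  invisible(x)
}

#' Simulate a cohort of participants
#'
#' Draws AQ scores spanning `trait_range`, maps each to ground-truth
#' learning parameters with [profile_from_trait()], and simulates one
#' session per participant and condition. Fully deterministic given
#' `config$seed`.
#'
#' @param config a [generator_config()].
#' @param n_participants cohort size (>= 2).
#' @param trait_range length-2 integer AQ range (within 0-50) the cohort
#'   spans.
#' @param conditions character vector of conditions to simulate.
#' @param mode localization mode passed to [simulate_session()].
#' @param profiles optional list of [participant_profile()]s (length
#'   `n_participants`) overriding the default trait mapping.
#' @return a list of `sim_session` objects with attribute `aq_scores`.
#' @export
simulate_cohort <- function(config = generator_config(), n_participants = 28,
                            trait_range = c(10, 28),
                            conditions = c("outward", "inward"),
                            mode = "fixation", profiles = NULL) {
  if (n_participants < 2) stop("n_participants must be at least 2")
  if (length(trait_range) != 2 || trait_range[1] > trait_range[2] ||
      trait_range[1] < 0 || trait_range[2] > 50)
    stop("trait_range must be an ordered pair within 0-50")
  aq <- as.integer(round(seq(trait_range[1], trait_range[2],
                             length.out = n_participants)))
  sessions <- list()
  for (i in seq_len(n_participants)) {
    for (j in seq_along(conditions)) {
      cond <- conditions[j]
      prof <- if (!is.null(profiles)) profiles[[i]]
              else profile_from_trait(aq[i], trait_range, cond)
      seed_ij <- (config$seed + 7919L * i + 104729L * j) %% 2147483629L
      s <- simulate_session(prof, config, condition = cond, mode = mode,
                            seed = seed_ij)
      s$participant <- i
      sessions[[length(sessions) + 1L]] <- s
    }
  }
  attr(sessions, "aq_scores") <- aq
  sessions
}
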