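# Shared fixtures: compact session configurations that keep the simulator's
# statistical structure but shrink trial counts for fast tests.

small_config <- function(seed = 1L, ...) {
  generator_config(n_saccade_trials = 44, n_baseline = 20, n_deadapt = 2,
                   seed = seed, ...)
}

noiseless_config <- function(seed = 1L, motor_noise_sd = 0,
                             loc_noise_sd = 0, ...) {
  small_config(seed = seed, motor_noise_sd = motor_noise_sd,
               loc_noise_sd = loc_noise_sd,
               fix_scatter = c(sigma_h = 0.01, sigma_v = 0.01, rho = 0), ...)
}

# a one-row trial stub for the validators
trial_stub <- function(fp_x = -6.5, fp_off_t = 100, click_x = NA,
                       t1_x = 6.5, t2_x = NA, displacement_t = NA,
                       flash_off_t = NA) {
  data.frame(fp_x = fp_x, fp_off_t = fp_off_t, click_x = click_x,
             t1_x = t1_x, t2_x = t2_x, displacement_t = displacement_t,
             flash_off_t = flash_off_t)
}

event_stub <- function(onset_t, offset_t, start_x, end_x) {
  data.frame(onset_t = onset_t, offset_t = offset_t, start_x = start_x,
             end_x = end_x, amplitude = end_x - start_x,
             duration = offset_t - onset_t, peak_velocity = 400,
             truncated = FALSE)
}
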