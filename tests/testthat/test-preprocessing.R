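flat_trace <- function(n = 200, x = 0) {
  data.frame(t_ms = seq_len(n) - 1, x_deg = x, y_deg = 0, pupil_valid = TRUE)
}

test_that("central-difference velocity is exact on constants and ramps", {
  v <- compute_velocity(flat_trace())
  expect_true(all(v$speed == 0))

  ramp <- flat_trace()
  ramp$x_deg <- ramp$t_ms / 10            # 1 deg per 10 ms
  v <- compute_velocity(ramp)
  expect_equal(v$speed, rep(100, nrow(ramp)), tolerance = 1e-9)

  expect_error(compute_velocity(flat_trace(2)), "3 samples")
})

test_that("velocity peak of a simulated saccade matches the profile formula", {
  cfg <- generator_config()
  tr <- simulate_saccade_trace(13, onset_ms = 60, config = cfg)
  v <- compute_velocity(tr)
  expect_equal(max(v$speed), saccade_peak_velocity(13, cfg),
               tolerance = 0.01 * saccade_peak_velocity(13, cfg))
})

test_that("saccade detection finds events at the analytic threshold crossing", {
  expect_equal(nrow(detect_saccades(flat_trace())), 0)

  cfg <- generator_config()
  tr <- simulate_saccade_trace(13, onset_ms = 60, config = cfg)
  ev <- detect_saccades(tr)
  expect_equal(nrow(ev), 1)
  cross <- 60 + 1000 * saccade_threshold_crossing(13, cfg)[["up"]]
  expect_lt(abs(ev$onset_t - cross), 2)
  expect_lt(abs(ev$amplitude - 13), 0.05)
  expect_gt(ev$duration, 30)

  # two saccades separated by 200 ms of fixation come out in order
  d1 <- saccade_duration_ms(8, cfg)
  t_ms <- 0:700
  x <- raised_sine_position(t_ms, 100, 8, d1) +
    raised_sine_position(t_ms, 100 + d1 + 200, 5, saccade_duration_ms(5, cfg))
  tr2 <- data.frame(t_ms = t_ms, x_deg = x, y_deg = 0, pupil_valid = TRUE)
  ev2 <- detect_saccades(tr2)
  expect_equal(nrow(ev2), 2)
  expect_lt(ev2$onset_t[1], ev2$onset_t[2])
  expect_equal(ev2$amplitude, c(8, 5), tolerance = 0.05)
})

test_that("detection is time-translation invariant and sign-equivariant", {
  cfg <- generator_config()
  tr <- simulate_saccade_trace(10, onset_ms = 60, config = cfg)
  shifted <- tr
  shifted$t_ms <- shifted$t_ms + 500
  a <- detect_saccades(tr); b <- detect_saccades(shifted)
  expect_equal(b$onset_t - a$onset_t, 500)
  expect_equal(b$amplitude, a$amplitude)

  flipped <- tr
  flipped$x_deg <- -flipped$x_deg
  c_ <- detect_saccades(flipped)
  expect_equal(c_$amplitude, -a$amplitude, tolerance = 1e-9)
  expect_equal(c_$onset_t, a$onset_t)
})

test_that("sub-saccadic velocity blips are suppressed by the duration criterion", {
  tr <- flat_trace(300)
  tr$x_deg[150:152] <- c(0.2, 0.4, 0.2)   # 3 ms transient above threshold
  ev <- detect_saccades(tr)
  expect_equal(nrow(ev), 0)
})

test_that("blink detection pads invalid runs and flags contaminated saccades", {
  expect_equal(nrow(detect_blinks(flat_trace())), 0)

  tr <- flat_trace(400)
  tr$pupil_valid[101:180] <- FALSE        # 80 ms gap
  b <- detect_blinks(tr)
  expect_equal(nrow(b), 1)
  expect_equal(b$start_t, 100 - 25)
  expect_equal(b$end_t, 179 + 25)

  # a blink overlapping the primary saccade invalidates the trial
  cfg <- generator_config()
  tr2 <- simulate_saccade_trace(13, onset_ms = 150, config = cfg,
                                fixation_x = -6.5)
  tr2$pupil_valid[tr2$t_ms > 160 & tr2$t_ms < 180] <- FALSE
  out <- validate_saccade_trial(trial_stub(fp_off_t = 100),
                                detect_saccades(tr2), detect_blinks(tr2))
  expect_false(out$valid)
  expect_equal(out$reasons, "blink_at_saccade")
})

test_that("saccade-trial rejection rules fire independently", {
  cfg <- generator_config()
  good <- detect_saccades(simulate_saccade_trace(13, 150, cfg,
                                                 fixation_x = -6.5))
  ok <- validate_saccade_trial(trial_stub(fp_off_t = 100), good,
                               data.frame(start_t = numeric(0),
                                          end_t = numeric(0)))
  expect_true(ok$valid)
  expect_equal(ok$amplitude, 13, tolerance = 0.05)

  small <- detect_saccades(simulate_saccade_trace(3, 150, cfg,
                                                  fixation_x = -6.5))
  out <- validate_saccade_trial(trial_stub(fp_off_t = 100), small, NULL)
  expect_equal(out$reasons, "amplitude_below_3.5")

  # saccade starting 50 ms before fixation offset
  early <- event_stub(50, 95, -6.5, -2.5)
  both <- rbind(early, event_stub(150, 192, -6.5, 6.5))
  out2 <- validate_saccade_trial(trial_stub(fp_off_t = 100), both, NULL)
  expect_equal(out2$reasons, "anticipatory_saccade")

  none <- detect_saccades(flat_trace())
  out3 <- validate_saccade_trial(trial_stub(fp_off_t = 100), none, NULL)
  expect_equal(out3$reasons, "no_presaccade")
  expect_true(is.na(out3$amplitude))
})

test_that("localization-trial rules enforce click eccentricity and the fixation window", {
  tr <- flat_trace(300, x = -6.5)
  ok <- validate_fixation_localization_trial(
    trial_stub(click_x = -6.5 + 13), tr)
  expect_true(ok$valid)

  out <- validate_fixation_localization_trial(trial_stub(click_x = -6.5 + 2),
                                              tr)
  expect_equal(out$reasons, "click_below_3.5")

  tr2 <- tr
  tr2$x_deg[100:120] <- -6.5 + 3          # 3 deg excursion from fixation
  out2 <- validate_fixation_localization_trial(
    trial_stub(click_x = -6.5 + 13), tr2)
  expect_equal(out2$reasons, "fixation_break")
  expect_lt(max(abs(tr$x_deg + 6.5)), 0.4)
})

test_that("post-saccadic localization requires a saccade after flash offset", {
  cfg <- generator_config()
  # saccade well after the flash: valid
  tr <- simulate_saccade_trace(13, 200, cfg, fixation_x = -6.5)
  ev <- detect_saccades(tr)
  ok <- validate_postsaccadic_localization_trial(
    trial_stub(click_x = -6.5 + 13.5, flash_off_t = 124), ev, tr)
  expect_true(ok$valid)

  # gaze never leaves the fixation window: no_presaccade
  flat <- flat_trace(400, x = -6.5)
  out <- validate_postsaccadic_localization_trial(
    trial_stub(click_x = -6.5 + 13.5, flash_off_t = 124),
    detect_saccades(flat), flat)
  expect_equal(out$reasons, "no_presaccade")

  # saccade during the 24 ms flash: saccade_before_extinction
  tr2 <- simulate_saccade_trace(13, 110, cfg, fixation_x = -6.5)
  out2 <- validate_postsaccadic_localization_trial(
    trial_stub(click_x = -6.5 + 13.5, flash_off_t = 124),
    detect_saccades(tr2), tr2)
  expect_equal(out2$reasons, "saccade_before_extinction")
})

test_that("displacement latency is measured from saccade onset and flagged", {
  ev <- event_stub(100, 145, -6.5, 6.5)
  r <- displacement_latency(trial_stub(displacement_t = 122), ev)
  expect_equal(r$latency_ms, 22)
  expect_true(r$intra_saccadic)

  r0 <- displacement_latency(trial_stub(displacement_t = 100), ev)
  expect_equal(r0$latency_ms, 0)
  expect_false(r0$intra_saccadic)

  r2 <- displacement_latency(trial_stub(displacement_t = 150), ev)
  expect_false(r2$intra_saccadic)

  r3 <- displacement_latency(trial_stub(), ev)
  expect_true(is.na(r3$latency_ms))
})

test_that("detected amplitudes recover the generative amplitude on clean sessions", {
  cfg <- noiseless_config(seed = 31)
  s <- simulate_session(profile_from_trait(12), cfg, "outward")
  pre <- preprocess_session(s)
  vs <- pre$trials[pre$trials$trial_type == "saccade" & pre$trials$valid, ]
  gt <- s$ground_truth[match(vs$block, s$ground_truth$block), ]
  expect_true(all(abs(vs$amplitude - gt$amplitude) < 0.05))
})
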