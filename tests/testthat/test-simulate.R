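test_that("adaptation state update follows the delta rule with retention", {
  expect_equal(update_adaptation_state(0, 3, alpha = 0.15, lam = 1), 0.45)
  expect_equal(update_adaptation_state(1.7, 2, alpha = 0, lam = 1), 1.7)
  expect_error(update_adaptation_state(NA, 1, 0.1, 1), "finite")

  # iterated updates under constant displacement reach the closed form
  g <- 0
  for (i in 1:10000) g <- update_adaptation_state(g, 3 - g, 0.15, 0.98)
  expect_equal(g, adaptation_asymptote(3, 0.15, 0.98), tolerance = 1e-10)
  expect_equal(adaptation_asymptote(3, 0.15, 0.98), 0.45 / 0.17,
               tolerance = 1e-12)

  # convergence to within 1e-6 of the asymptote inside 500 iterations
  g <- 0
  for (i in 1:500) g <- update_adaptation_state(g, 3 - g, 0.15, 0.98)
  expect_lt(abs(g - adaptation_asymptote(3, 0.15, 0.98)), 1e-6)
})

test_that("raised-sine saccade traces have exact amplitude and analytic kinematics", {
  cfg <- generator_config()
  tr <- simulate_saccade_trace(13, onset_ms = 50, config = cfg)
  expect_equal(max(tr$x_deg) - min(tr$x_deg), 13, tolerance = 1e-9)

  d <- saccade_duration_ms(13, cfg) / 1000
  expect_equal(saccade_peak_velocity(13, cfg), pi * 13 / (2 * d))

  # threshold crossing matches the analytic inversion of the profile
  cross <- saccade_threshold_crossing(13, cfg, threshold = 30)
  expect_equal(cross[["up"]], (d / pi) * asin(60 * d / (pi * 13)))
  # the velocity at the crossing time is the threshold
  v <- function(t) (pi * 13 / (2 * d)) * sin(pi * t / d)
  expect_equal(v(cross[["up"]]), 30, tolerance = 1e-9)
  expect_equal(v(cross[["down"]]), 30, tolerance = 1e-9)

  expect_error(simulate_saccade_trace(-2, 50), "positive")
  expect_error(simulate_saccade_trace(0, 50), "positive")
})

test_that("fixation scatter reproduces the requested bivariate moments", {
  cfg0 <- generator_config(fix_scatter = c(sigma_h = 0, sigma_v = 0, rho = 0))
  s <- simulate_fixation_scatter(100, cfg0, center = c(1, -2))
  expect_true(all(s$x == 1) && all(s$y == -2))

  cfg <- generator_config(fix_scatter = c(sigma_h = 1, sigma_v = 1, rho = 0.5))
  set.seed(11)
  s <- simulate_fixation_scatter(2e5, cfg)
  expect_equal(cor(s$x, s$y), 0.5, tolerance = 0.01)
  expect_equal(sd(s$x), 1, tolerance = 0.01)

  set.seed(7); a <- simulate_fixation_scatter(50, cfg)
  set.seed(7); b <- simulate_fixation_scatter(50, cfg)
  expect_identical(a, b)

  expect_error(generator_config(
    fix_scatter = c(sigma_h = 1, sigma_v = 1, rho = 1)), "rho")
})

test_that("seeded sessions are bit-reproducible", {
  cfg <- small_config(seed = 21)
  p <- profile_from_trait(14)
  a <- simulate_session(p, cfg, "outward")
  b <- simulate_session(p, cfg, "outward")
  expect_identical(a$gaze, b$gaze)
  expect_identical(a$trials, b$trials)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("cohort generation spans the trait range and rejects bad input", {
  cfg <- small_config(seed = 2)
  sessions <- simulate_cohort(cfg, n_participants = 5,
                              trait_range = c(10, 28),
                              conditions = "outward")
  expect_length(sessions, 5)
  aq <- attr(sessions, "aq_scores")
  expect_true(all(aq >= 10 & aq <= 28))
  expect_equal(range(aq), c(10, 28))

  two <- simulate_cohort(cfg, 2, c(10, 28), conditions = "outward")
  two_again <- simulate_cohort(cfg, 2, c(10, 28), conditions = "outward")
  expect_identical(two[[1]]$gaze, two_again[[1]]$gaze)

  expect_error(simulate_cohort(cfg, 1), "at least 2")
  expect_error(simulate_cohort(cfg, 4, trait_range = c(-3, 20)), "trait_range")
  expect_error(simulate_cohort(cfg, 4, trait_range = c(20, 60)), "trait_range")
})

test_that("localization clicks decompose into the stated generative terms", {
  # all couplings and noise at zero: clicks sit exactly at 13 deg
  cfg <- noiseless_config(seed = 5)
  p0 <- participant_profile(15, alpha = 0, lam = 0.98, gamma = 0, kappa = 0)
  s <- simulate_session(p0, cfg, "outward")
  loc <- s$trials[s$trials$trial_type == "localization_fixation", ]
  expect_equal(loc$click_x - loc$fp_x, rep(13, nrow(loc)), tolerance = 1e-9)

  # pure serial coupling: click eccentricity = 13 + gamma * previous error
  pg <- participant_profile(15, alpha = 0, lam = 0.98, gamma = 0.5, kappa = 0)
  cfg2 <- noiseless_config(seed = 6, motor_noise_sd = 0.3)
  s2 <- simulate_session(pg, cfg2, "outward")
  loc2 <- s2$trials[s2$trials$trial_type == "localization_fixation", ]
  err <- s2$ground_truth$saccade_error[match(loc2$block,
                                             s2$ground_truth$block)]
  expect_equal(loc2$click_x - loc2$fp_x, 13 + 0.5 * err, tolerance = 1e-9)
})

test_that("perceptual map drifts under outward displacement even when alpha = 0", {
  cfg <- noiseless_config(seed = 9, loc_noise_sd = 0)
  p <- participant_profile(20, alpha = 0, lam = 0.98, gamma = 0,
                           kappa = 0, alpha_p = 0.1)
  s <- simulate_session(p, cfg, "outward", mode = "post_saccadic")
  loc <- s$trials[s$trials$trial_type == "localization_postsaccadic", ]
  base <- loc$click_x[loc$phase_true == "baseline"]
  adapt <- loc$click_x[loc$phase_true == "adaptation"]
  expect_gt(mean(adapt), mean(base))
  # motor state stays frozen at zero while perception shifts
  expect_true(all(s$ground_truth$g_post == 0))
  expect_gt(max(s$ground_truth$p_post), 0.5)
})

test_that("displacements land strictly inside the executed saccade", {
  cfg <- small_config(seed = 13)
  s <- simulate_session(profile_from_trait(12), cfg, "outward")
  pre <- preprocess_session(s)
  sac <- pre$trials[pre$trials$trial_type == "saccade" &
                      !is.na(pre$trials$displacement_t), ]
  expect_true(all(sac$intra_saccadic, na.rm = TRUE))
  lat <- sac$latency_ms[!is.na(sac$latency_ms)]
  expect_true(all(lat > 18 & lat < 26))
})
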