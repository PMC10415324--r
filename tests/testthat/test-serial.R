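test_that("error sign conventions follow the paradigm geometry", {
  # eye lands at 13 deg, outward-displaced target at 16 deg: error +3
  tr <- trial_stub(t2_x = 6.5 + 3)
  ev <- event_stub(150, 195, -6.5, -6.5 + 13)
  expect_equal(saccade_error(tr, ev)$error, 3)

  ev2 <- event_stub(150, 195, -6.5, 6.5 + 3)
  expect_equal(saccade_error(tr, ev2)$error, 0)

  # inward: landing 10.5 with target at 10 gives -0.5
  tr3 <- trial_stub(t2_x = 6.5 - 3)
  ev3 <- event_stub(150, 195, -6.5, -6.5 + 10.5)
  expect_equal(saccade_error(tr3, ev3)$error, -0.5)

  # missing displaced target falls back to T1 with a flag
  tr4 <- trial_stub(t2_x = NA)
  ev_sh <- event_stub(150, 195, -6.5, -6.5 + 12)   # 1 deg undershoot
  r4 <- saccade_error(tr4, ev_sh)
  expect_true(r4$against_t1)
  expect_equal(r4$error, 1)

  # localization errors: negative = foveal
  expect_equal(localization_error(trial_stub(click_x = -6.5 + 13)), 0)
  expect_equal(localization_error(trial_stub(click_x = -6.5 + 12)), -1)
  expect_equal(localization_error(trial_stub(click_x = -6.5 + 14.5)), 1.5)
})

make_pair_trials <- function(n_blocks, sacc_valid = rep(TRUE, n_blocks),
                             loc_valid = rep(TRUE, n_blocks)) {
  sacc <- data.frame(trial_id = 2 * seq_len(n_blocks) - 1,
                     block = seq_len(n_blocks), trial_type = "saccade",
                     valid = sacc_valid, phase = "adaptation",
                     fp_x = -6.5, t1_x = 6.5, t2_x = 9.5,
                     amplitude = 13 + seq_len(n_blocks) / 10,
                     click_x = NA)
  loc <- data.frame(trial_id = 2 * seq_len(n_blocks),
                    block = seq_len(n_blocks),
                    trial_type = "localization_fixation",
                    valid = loc_valid, phase = "adaptation",
                    fp_x = -6.5, t1_x = 6.5, t2_x = NA, amplitude = NA,
                    click_x = -6.5 + 13.2)
  rbind(sacc, loc)
}

test_that("lag-1 pairing keeps only valid saccade/localization couples", {
  trials <- make_pair_trials(10)
  p <- build_lagged_pairs(trials)
  expect_equal(nrow(p), 10)
  # saccade error = t2 - (fp + amplitude)
  expect_equal(p$saccade_error_prev, 9.5 - (-6.5 + 13 + 1:10 / 10))

  sv <- rep(TRUE, 10); sv[5] <- FALSE
  p2 <- build_lagged_pairs(make_pair_trials(10, sacc_valid = sv))
  expect_equal(nrow(p2), 9)
  expect_false(5 %in% p2$block)

  empty <- build_lagged_pairs(make_pair_trials(10)[0, ])
  expect_equal(nrow(empty), 0)

  # de-adaptation pairs are excluded
  trials3 <- make_pair_trials(10)
  trials3$phase[trials3$block > 7] <- "deadaptation"
  expect_equal(nrow(build_lagged_pairs(trials3)), 7)
})

test_that("sliding-window binning follows the stated width and start grid", {
  pairs <- data.frame(block = 1:100,
                      saccade_error_prev = seq(-2, 2, length.out = 100),
                      localization_error = rnorm(100))
  b <- bin_pairs(pairs, n_bins = 24, frac = 1 / 5)
  expect_equal(unique(b$n_in_bin), 20)           # width = n/5
  expect_equal(nrow(b), 24)
  starts <- round(seq(1, 100 - 20 + 1, length.out = 24))
  expect_equal(starts[1:3], c(1, 4, 8))
  expect_equal(starts[24], 81)

  cpairs <- pairs
  cpairs$saccade_error_prev <- 1; cpairs$localization_error <- 2
  bc <- bin_pairs(cpairs)
  expect_true(all(bc$saccade_error_prev == 1 & bc$localization_error == 2))

  b1 <- bin_pairs(pairs, n_bins = 1, frac = 1)
  expect_equal(b1$saccade_error_prev, mean(pairs$saccade_error_prev))
  expect_equal(b1$localization_error, mean(pairs$localization_error))

  expect_warning(bu <- bin_pairs(pairs[1:5, ]), "fewer pairs")
  expect_equal(nrow(bu), 5)
})

test_that("width-1 binning reproduces the unbinned regression exactly", {
  set.seed(12)
  pairs <- data.frame(block = 1:60,
                      saccade_error_prev = rnorm(60),
                      localization_error = rnorm(60))
  b <- bin_pairs(pairs, n_bins = 60, frac = 1 / 60)
  s <- serial_slope(b)
  raw <- unname(coef(lm(localization_error ~ saccade_error_prev, pairs))[2])
  expect_equal(s$slope, raw, tolerance = 1e-12)
})

test_that("noiseless generative sessions return the planted serial slope", {
  cfg <- noiseless_config(seed = 41, motor_noise_sd = 0.3)
  p <- participant_profile(15, alpha = 0, lam = 0.98, gamma = 0.5, kappa = 0)
  s <- simulate_session(p, cfg, "outward")

  # generative identity: regressing clicks on the true post-saccadic
  # errors returns gamma exactly
  loc <- s$trials[s$trials$trial_type == "localization_fixation" &
                    s$trials$phase_true != "deadaptation", ]
  err <- s$ground_truth$saccade_error[match(loc$block,
                                            s$ground_truth$block)]
  gpairs <- data.frame(block = loc$block, saccade_error_prev = err,
                       localization_error = (loc$click_x - loc$fp_x) - 13)
  expect_equal(serial_slope(bin_pairs(gpairs))$slope, 0.5, tolerance = 1e-6)

  # full measured route: detector-resolution landing positions leave the
  # recovered slope within detector precision of gamma
  pre <- preprocess_session(s)
  trials <- pre$trials
  trials$phase <- trials$phase_true
  pairs <- build_lagged_pairs(trials)
  sr <- serial_slope(bin_pairs(pairs))
  expect_equal(sr$slope, 0.5, tolerance = 0.01)

  # additive shifts of localization go into the intercept only
  shifted <- pairs
  shifted$localization_error <- shifted$localization_error + 1.3
  sr2 <- serial_slope(bin_pairs(shifted))
  expect_equal(sr2$slope, sr$slope, tolerance = 1e-9)
  expect_equal(sr2$intercept, sr$intercept + 1.3, tolerance = 1e-9)

  # attraction property: adding c * previous error raises the slope by c
  boosted <- pairs
  boosted$localization_error <- boosted$localization_error +
    0.2 * boosted$saccade_error_prev
  expect_equal(serial_slope(bin_pairs(boosted))$slope, sr$slope + 0.2,
               tolerance = 1e-9)
})

test_that("null and intermediate couplings are recovered within simulation error", {
  slopes <- sapply(c(0, 0.3), function(gam) {
    mean(vapply(1:4, function(i) {
      cfg <- small_config(seed = 500 + 10 * gam * 10 + i)
      p <- participant_profile(15, alpha = 0.15, lam = 0.98, gamma = gam,
                               kappa = 0)
      s <- simulate_session(p, cfg, "outward")
      pre <- preprocess_session(s)
      trials <- pre$trials
      trials$phase <- trials$phase_true
      sr <- serial_slope(bin_pairs(build_lagged_pairs(trials)))
      sr$slope
    }, numeric(1)))
  })
  expect_lt(abs(slopes[1]), 0.1)
  expect_gt(slopes[2], 0.15)
  expect_lt(slopes[2], 0.45)

  # zero x-spread is flagged as degenerate, not silently regressed
  const <- data.frame(saccade_error_prev = rep(1, 5),
                      localization_error = rnorm(5), n_in_bin = 1)
  expect_true(serial_slope(const)$degenerate)
})
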