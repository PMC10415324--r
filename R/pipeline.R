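## End-to-end orchestration: simulate -> preprocess -> analyze -> report.

#' Full pipeline configuration
#'
#' Collects every tunable of the pipeline with the paradigm's values as
#' defaults: generator settings, detection threshold, rejection limits,
#' phase windows, BCEA confidence limit and formula variant, serial binning
#' and the Bayes-factor prior scale. The configuration round-trips
#' losslessly through [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param experiment `"exp1_outward"`, `"exp1_inward"`, `"exp1"` (both
#'   exp1 conditions) or `"exp2"` (outward with post-saccadic
#'   localization).
#' @param n_participants cohort size.
#' @param trait_range AQ range the cohort spans.
#' @param generator a [generator_config()].
#' @param threshold,min_duration_ms saccade detection parameters (deg/s,
#'   ms).
#' @param min_amplitude minimum landing/click eccentricity, deg.
#' @param fix_window_radius fixation window radius, deg.
#' @param n_window trials averaged at each end for the adaptation
#'   magnitude.
#' @param k BCEA confidence limit.
#' @param bcea_formula `"as_printed"` or `"standard"`.
#' @param n_bins,bin_frac,binning_mode serial-dependence binning.
#' @param prior_scale JZS Cauchy prior scale.
#' @param seed master seed (overrides the generator's).
#' @param out_dir optional output directory for [run_pipeline()] tables.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(experiment = c("exp1", "exp1_outward",
                                           "exp1_inward", "exp2"),
                            n_participants = 28, trait_range = c(10, 28),
                            generator = generator_config(),
                            threshold = 30, min_duration_ms = 10,
                            min_amplitude = 3.5, fix_window_radius = 2.5,
                            n_window = 20, k = 1.14,
                            bcea_formula = "as_printed",
                            n_bins = 24, bin_frac = 1 / 5,
                            binning_mode = "sliding",
                            prior_scale = sqrt(2) / 2,
                            seed = 1L, out_dir = NULL) {
  experiment <- match.arg(experiment)
  generator$seed <- as.integer(seed)
  validate_generator_config(generator)
  stopifnot(threshold > 0, min_duration_ms >= 0, min_amplitude > 0,
            fix_window_radius > 0, n_window >= 1, k >= 0,
            n_bins >= 1, bin_frac > 0, bin_frac <= 1, prior_scale > 0)
  bcea_formula <- match.arg(bcea_formula, c("as_printed", "standard"))
  binning_mode <- match.arg(binning_mode, c("sliding", "quantile"))
  structure(list(experiment = experiment,
                 n_participants = n_participants, trait_range = trait_range,
                 generator = generator, threshold = threshold,
                 min_duration_ms = min_duration_ms,
                 min_amplitude = min_amplitude,
                 fix_window_radius = fix_window_radius,
                 n_window = n_window, k = k, bcea_formula = bcea_formula,
                 n_bins = n_bins, bin_frac = bin_frac,
                 binning_mode = binning_mode, prior_scale = prior_scale,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

experiment_plan <- function(experiment) {
  switch(experiment,
         exp1 = list(conditions = c("outward", "inward"), mode = "fixation"),
         exp1_outward = list(conditions = "outward", mode = "fixation"),
         exp1_inward = list(conditions = "inward", mode = "fixation"),
         exp2 = list(conditions = "outward", mode = "post_saccadic"))
}

#' Analyze one preprocessed session
#'
#' Labels phases on the valid trials, computes saccade and localization
#' adaptation magnitudes, fits the exponential time course to the
#' adaptation-phase saccade amplitudes (x = valid-trial index), extracts
#' the lag-1 serial-dependence slope, and summarizes fixation stability
#' (BCEA and mean gaze offset) from the localization-trial gaze samples.
#'
#' @param pre a [preprocess_session()] result.
#' @param config a [pipeline_config()].
#' @return one-row data.frame of per-participant results (NULL when the
#'   session is unanalyzable).
#' @export
analyze_session <- function(pre, config = pipeline_config()) {
  trials <- pre$trials
  gen <- pre$config
  ecc <- gen$target_x - gen$fixation_x
  is_sacc <- trials$trial_type == "saccade"
  is_loc <- grepl("^localization", trials$trial_type)

  vs <- trials[is_sacc & trials$valid, , drop = FALSE]
  phases_s <- label_phases(nrow(vs), gen$n_baseline, gen$n_deadapt)
  if (is.null(phases_s)) return(NULL)
  vl <- trials[is_loc & trials$valid, , drop = FALSE]
  phases_l <- label_phases(nrow(vl), gen$n_baseline, gen$n_deadapt)
  if (is.null(phases_l)) return(NULL)

  # propagate the valid-order phase labels back onto the trial table
  trials$phase <- NA_character_
  trials$phase[match(vs$trial_id, trials$trial_id)] <- phases_s
  trials$phase[match(vl$trial_id, trials$trial_id)] <- phases_l

  mag_s <- adaptation_magnitude(vs$amplitude, phases_s, config$n_window)
  mag_l <- adaptation_magnitude(vl$amplitude, phases_l, config$n_window)

  xfit <- which(phases_s == "adaptation")
  fit <- fit_exponential(xfit, vs$amplitude[phases_s == "adaptation"])

  pairs <- build_lagged_pairs(trials, eccentricity = ecc)
  slope <- intercept <- NA_real_
  if (nrow(pairs) >= 3) {
    binned <- suppressWarnings(
      bin_pairs(pairs, n_bins = config$n_bins, frac = config$bin_frac,
                mode = config$binning_mode))
    sr <- serial_slope(binned)
    if (!sr$degenerate) { slope <- sr$slope; intercept <- sr$intercept }
  }

  # fixation-phase gaze of valid localization trials
  gz <- pre$gaze[pre$gaze$trial_id %in% vl$trial_id, , drop = FALSE]
  if (pre$mode == "post_saccadic") {
    flash_on <- setNames(vl$flash_on_t, vl$trial_id)
    gz <- gz[gz$t_ms <= flash_on[as.character(gz$trial_id)], , drop = FALSE]
  }
  bc <- tryCatch(bcea(gz$x_deg, gz$y_deg, k = config$k,
                      formula = config$bcea_formula),
                 error = function(e) NULL)
  off <- mean_gaze_offset(gz$x_deg - gen$fixation_x, gz$y_deg,
                          trial = gz$trial_id)

  lat <- trials$latency_ms[is_sacc & trials$valid]
  dur <- trials$duration[is_sacc & trials$valid]
  data.frame(
    participant = pre$participant %||% NA_integer_,
    condition = pre$condition, mode = pre$mode,
    aq = pre$profile$aq_score,
    n_valid_saccade = nrow(vs), n_valid_localization = nrow(vl),
    magnitude_saccade = mag_s$magnitude,
    magnitude_localization = mag_l$magnitude,
    y0 = fit$y0, A = fit$A, R0 = fit$R0, rss = fit$rss,
    fit_converged = fit$converged,
    slope = slope, intercept = intercept, n_pairs = nrow(pairs),
    bcea = if (is.null(bc)) NA_real_ else bc$bcea,
    sigma_h = if (is.null(bc)) NA_real_ else bc$sigma_h,
    sigma_v = if (is.null(bc)) NA_real_ else bc$sigma_v,
    rho = if (is.null(bc)) NA_real_ else bc$rho,
    gaze_offset = off$offset,
    mean_latency_ms = mean(lat, na.rm = TRUE),
    mean_duration_ms = mean(dur, na.rm = TRUE),
    stringsAsFactors = FALSE)
}

#' Group statistics for a cohort results table
#'
#' Splits participants into low/high trait groups by the AQ median
#' ([median_split()]) and, per condition, compares adaptation magnitudes
#' and serial slopes between groups (pooled two-sample t with JZS Bayes
#' factor) and correlates each with AQ.
#'
#' @param participants the per-participant table from [run_pipeline()].
#' @param prior_scale JZS prior scale.
#' @return data.frame with one row per comparison: `condition`, `measure`,
#'   `type` (`t_test` or `correlation`), `statistic`, `df_or_n`, `p`,
#'   `log10_bf`, `band`, plus the AQ `median` used.
#' @export
group_statistics <- function(participants, prior_scale = sqrt(2) / 2) {
  out <- list()
  for (cond in unique(participants$condition)) {
    d <- participants[participants$condition == cond, , drop = FALSE]
    sp <- median_split(d$aq)
    measures <- c("magnitude_saccade", "magnitude_localization", "slope",
                  "bcea", "gaze_offset")
    for (m in measures) {
      v <- d[[m]]
      lo <- v[sp$low]; hi <- v[sp$high]
      lo <- lo[is.finite(lo)]; hi <- hi[is.finite(hi)]
      if (length(lo) >= 2 && length(hi) >= 2) {
        tt <- t_test_two_sample(lo, hi, prior_scale = prior_scale)
        out[[length(out) + 1L]] <- data.frame(
          condition = cond, measure = m, type = "t_test",
          statistic = tt$t, df_or_n = tt$df, p = tt$p,
          log10_bf = tt$log10_bf, band = tt$band, aq_median = sp$median,
          stringsAsFactors = FALSE)
      }
      keep <- is.finite(v)
      if (sum(keep) >= 3 && stats::sd(v[keep]) > 0) {
        ct <- pearson_correlation(d$aq[keep], v[keep])
        out[[length(out) + 1L]] <- data.frame(
          condition = cond, measure = m, type = "correlation",
          statistic = ct$r, df_or_n = ct$n, p = ct$p,
          log10_bf = ct$log10_bf, band = ct$band, aq_median = sp$median,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Run the full pipeline
#'
#' Simulates a cohort under the configured experiment, preprocesses every
#' session (detection + rejection rules), analyzes each one
#' ([analyze_session()]) and computes group statistics. When
#' `config$out_dir` is set the per-participant table, group statistics and
#' rejection log are also written as CSV and the configuration as JSON.
#'
#' @param config a [pipeline_config()].
#' @return object of class `saccadapt_report`: list with `participants`
#'   (per-session results), `group_stats`, `rejections` (trial-level log of
#'   every rejected trial with reasons), `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config"))
    stop("config must be a pipeline_config")
  plan <- experiment_plan(config$experiment)
  sessions <- simulate_cohort(config$generator,
                              n_participants = config$n_participants,
                              trait_range = config$trait_range,
                              conditions = plan$conditions,
                              mode = plan$mode)
  rows <- list(); rej <- list()
  for (s in sessions) {
    pre <- preprocess_session(
      s, threshold = config$threshold,
      min_duration_ms = config$min_duration_ms,
      min_amplitude = config$min_amplitude,
      fix_window_radius = config$fix_window_radius)
    row <- suppressWarnings(analyze_session(pre, config))
    if (!is.null(row)) rows[[length(rows) + 1L]] <- row
    bad <- pre$trials[!pre$trials$valid,
                      c("trial_id", "block", "trial_type", "reasons"),
                      drop = FALSE]
    if (nrow(bad) > 0) {
      bad$participant <- s$participant
      bad$condition <- s$condition
      rej[[length(rej) + 1L]] <- bad
    }
  }
  report <- structure(list(
    participants = do.call(rbind, rows),
    group_stats = if (length(rows) > 0)
      group_statistics(do.call(rbind, rows),
                       prior_scale = config$prior_scale) else NULL,
    rejections = if (length(rej) > 0) do.call(rbind, rej)
                 else data.frame(),
    config = config), class = "saccadapt_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.saccadapt_report <- function(x, ...) {
  cat(sprintf("<saccadapt_report> %s | %d sessions analyzed, %d trials rejected\n",
              x$config$experiment,
              if (is.null(x$participants)) 0L else nrow(x$participants),
              if (is.null(x$rejections)) 0L else nrow(x$rejections)))
  if (!is.null(x$group_stats)) {
    cat("group statistics:\n")
    print(x$group_stats, digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' Build the frozen test fixture set
#'
#' Constructs two small deterministic sessions carrying exactly one
#' planted violation of each rejection class: an undersized saccade
#' (amplitude 3.0), a blink during the saccade, an anticipatory saccade
#' before fixation offset, a trial without any saccade, a click below 3.5
#' degrees, a fixation break during localization (experiment-1 session),
#' and a saccade initiated during the flash (experiment-2 session). All
#' other trials are noise-free and valid, so preprocessing must recover
#' exactly the planted counts.
#'
#' @param seed integer seed.
#' @param dir optional directory; when given, both sessions are written as
#'   delimited text via [write_session()].
#' @return list with `exp1`, `exp2` (sim_session objects), `expected`
#'   (named vector of planted rejection-reason counts), and `files`.
#' @export
make_fixtures <- function(seed = 1L, dir = NULL) {
  cfg <- generator_config(n_saccade_trials = 12, n_baseline = 3,
                          n_deadapt = 3, motor_noise_sd = 0,
                          loc_noise_sd = 0,
                          fix_scatter = c(sigma_h = 0.05, sigma_v = 0.05,
                                          rho = 0),
                          seed = seed)
  prof <- participant_profile(15, alpha = 0.15, lam = 0.98, gamma = 0.3)
  s1 <- simulate_session(prof, cfg, condition = "outward",
                         mode = "fixation", seed = seed)
  fp <- cfg$fixation_x

  replace_trace <- function(session, id, trace) {
    trace$trial_id <- id
    rest <- session$gaze[session$gaze$trial_id != id, , drop = FALSE]
    session$gaze <- rbind(rest, trace)
    session$gaze <- session$gaze[order(session$gaze$trial_id,
                                       session$gaze$t_ms), , drop = FALSE]
    session
  }
  trial_row <- function(session, id) which(session$trials$trial_id == id)

  # block 4 saccade (trial 7): amplitude 3.0 -> amplitude_below_3.5
  id <- 7L
  tr <- simulate_saccade_trace(3, onset_ms = 280, config = cfg,
                               fixation_x = fp)
  s1 <- replace_trace(s1, id, tr)

  # block 5 saccade (trial 9): blink overlapping the saccade
  id <- 9L
  g <- s1$gaze[s1$gaze$trial_id == id, ]
  move_t <- g$t_ms[which(abs(g$x_deg - fp) > 0.5)[1]]  # inside the saccade
  mid <- g$t_ms > move_t & g$t_ms < move_t + 30
  s1$gaze$pupil_valid[s1$gaze$trial_id == id][mid] <- FALSE

  # block 6 saccade (trial 11): extra 4-deg saccade before fixation offset,
  # main saccade intact afterwards -> anticipatory_saccade only
  id <- 11L
  fp_off <- s1$trials$fp_off_t[trial_row(s1, id)]
  t_ms <- seq(0, 500)
  x <- fp + raised_sine_position(t_ms, 20, 4, saccade_duration_ms(4, cfg)) +
    raised_sine_position(t_ms, fp_off + 150, 9, saccade_duration_ms(9, cfg))
  s1 <- replace_trace(s1, id, data.frame(t_ms = t_ms, x_deg = x, y_deg = 0,
                                         pupil_valid = TRUE))

  # block 7 saccade (trial 13): no saccade at all -> no_presaccade
  id <- 13L
  t_ms <- seq(0, 400)
  s1 <- replace_trace(s1, id, data.frame(t_ms = t_ms, x_deg = fp, y_deg = 0,
                                         pupil_valid = TRUE))

  # block 8 localization (trial 16): click at 2 deg -> click_below_3.5
  s1$trials$click_x[trial_row(s1, 16L)] <- fp + 2

  # block 9 localization (trial 18): gaze excursion to 3 deg ->
  # fixation_break
  id <- 18L
  g <- s1$gaze$trial_id == id
  seg <- which(g)[150:200]
  s1$gaze$x_deg[seg] <- fp + 3.2

  # exp2 session with one saccade during the flash
  s2 <- simulate_session(prof, cfg, condition = "outward",
                         mode = "post_saccadic", seed = seed + 1L)
  id <- 8L   # block 4 localization
  row <- trial_row(s2, id)
  flash_on <- s2$trials$flash_on_t[row]
  t_ms <- seq(0, 500)
  x <- fp + raised_sine_position(t_ms, flash_on + 10, 13,
                                 saccade_duration_ms(13, cfg))
  s2 <- replace_trace(s2, id, data.frame(t_ms = t_ms, x_deg = x, y_deg = 0,
                                         pupil_valid = TRUE))

  expected <- c(amplitude_below_3.5 = 1, blink_at_saccade = 1,
                anticipatory_saccade = 1, no_presaccade = 1,
                click_below_3.5 = 1, fixation_break = 1,
                saccade_before_extinction = 1)
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(write_session(s1, dir, "fixture_exp1"),
               write_session(s2, dir, "fixture_exp2"))
  }
  list(exp1 = s1, exp2 = s2, expected = expected, files = files)
}
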