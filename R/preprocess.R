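## Gaze preprocessing: velocity, saccade/blink detection, trial rejection.

#' Two-dimensional gaze velocity by central differences
#'
#' Velocity at sample i is `(pos[i+1] - pos[i-1]) / (t[i+1] - t[i-1])`
#' componentwise (one-sided differences at the endpoints); speed is the
#' Euclidean norm of the two component velocities. Positions are used
#' unsmoothed by default; an optional 5-sample moving average can be applied
#' first, but smoothing is off by default so that it cannot silently move
#' detected onsets.
#'
#' @param trace data.frame with columns `t_ms`, `x_deg`, `y_deg`.
#' @param smooth logical; apply a 5-sample moving average to positions
#'   before differentiating.
#' @return data.frame with columns `t_ms`, `vx`, `vy`, `speed` (deg/s) and
#'   `gap` (TRUE where the local sample spacing exceeds 2 ms).
#' @export
compute_velocity <- function(trace, smooth = FALSE) {
  n <- nrow(trace)
  if (n < 3) stop("compute_velocity requires at least 3 samples")
  t <- trace$t_ms
  if (any(diff(t) <= 0)) stop("t_ms must be strictly increasing")
  x <- trace$x_deg; y <- trace$y_deg
  if (smooth) {
    ker <- rep(1 / 5, 5)
    pad <- function(z) c(z[1], z[1], z, z[n], z[n])
    x <- stats::filter(pad(x), ker, sides = 2)[3:(n + 2)]
    y <- stats::filter(pad(y), ker, sides = 2)[3:(n + 2)]
  }
  vx <- vy <- numeric(n)
  dt2 <- t[3:n] - t[1:(n - 2)]
  vx[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / dt2
  vy[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / dt2
  vx[1] <- (x[2] - x[1]) / (t[2] - t[1])
  vy[1] <- (y[2] - y[1]) / (t[2] - t[1])
  vx[n] <- (x[n] - x[n - 1]) / (t[n] - t[n - 1])
  vy[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
  gap <- c(FALSE, diff(t) > 2)
  data.frame(t_ms = t, vx = vx * 1000, vy = vy * 1000,
             speed = sqrt(vx^2 + vy^2) * 1000, gap = gap)
}

#' Detect saccades by a velocity threshold
#'
#' An event spans each maximal run of samples whose speed exceeds
#' `threshold` (default 30 deg/s, the criterion used online by the tracker)
#' and that lasts at least `min_duration_ms`. Onset is the first
#' supra-threshold sample and offset the first sub-threshold sample after
#' the run. Start and end positions are refined by linear interpolation of
#' the speed trace to the exact threshold crossing, which keeps amplitude
#' estimates accurate at 1 kHz sampling; amplitude is `end_x - start_x`
#' along the horizontal axis.
#'
#' @param trace data.frame with `t_ms`, `x_deg`, `y_deg`.
#' @param threshold speed threshold, deg/s.
#' @param min_duration_ms minimum event duration, ms; suppresses
#'   noise-triggered events well below any goal-directed saccade.
#' @param velocity optional precomputed [compute_velocity()] output.
#' @return data.frame of class `saccade_events` with columns `onset_t`,
#'   `offset_t`, `start_x`, `end_x`, `amplitude`, `duration`,
#'   `peak_velocity`, `truncated` (event still above threshold at trace
#'   end). Zero rows when nothing is detected.
#' @export
detect_saccades <- function(trace, threshold = 30, min_duration_ms = 10,
                            velocity = NULL) {
  if (is.null(velocity)) velocity <- compute_velocity(trace)
  sp <- velocity$speed
  t <- velocity$t_ms
  n <- length(sp)
  above <- sp > threshold
  empty <- data.frame(onset_t = numeric(0), offset_t = numeric(0),
                      start_x = numeric(0), end_x = numeric(0),
                      amplitude = numeric(0), duration = numeric(0),
                      peak_velocity = numeric(0), truncated = logical(0))
  class(empty) <- c("saccade_events", "data.frame")
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  out <- list()
  for (ri in runs) {
    i0 <- starts[ri]                 # first supra-threshold sample
    i1 <- ends[ri] + 1               # first sub-threshold sample after
    truncated <- i1 > n
    if (truncated) i1 <- n
    if (t[i1] - t[i0] < min_duration_ms) next
    # sub-sample refinement of the boundary positions
    start_x <- if (i0 > 1) {
      f <- (threshold - sp[i0 - 1]) / (sp[i0] - sp[i0 - 1])
      trace$x_deg[i0 - 1] + f * (trace$x_deg[i0] - trace$x_deg[i0 - 1])
    } else trace$x_deg[i0]
    end_x <- if (!truncated && sp[i1 - 1] > sp[i1]) {
      f <- (sp[i1 - 1] - threshold) / (sp[i1 - 1] - sp[i1])
      trace$x_deg[i1 - 1] + f * (trace$x_deg[i1] - trace$x_deg[i1 - 1])
    } else trace$x_deg[i1]
    out[[length(out) + 1L]] <- data.frame(
      onset_t = t[i0], offset_t = t[i1],
      start_x = start_x, end_x = end_x,
      amplitude = end_x - start_x,
      duration = t[i1] - t[i0],
      peak_velocity = max(sp[i0:(i1 - 1)]),
      truncated = truncated)
  }
  if (length(out) == 0) return(empty)
  ev <- do.call(rbind, out)
  ev <- ev[order(ev$onset_t), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("saccade_events", "data.frame")
  ev
}

#' Detect blinks from pupil validity
#'
#' Maximal runs of invalid pupil samples, padded by `pad_ms` on both sides
#' to cover the distorted gaze samples at blink edges.
#'
#' @param trace data.frame with `t_ms` and logical `pupil_valid`.
#' @param pad_ms padding applied to each side of a run, ms.
#' @return data.frame with columns `start_t`, `end_t` (zero rows if none).
#' @export
detect_blinks <- function(trace, pad_ms = 25) {
  bad <- !trace$pupil_valid
  if (!any(bad)) return(data.frame(start_t = numeric(0), end_t = numeric(0)))
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  data.frame(start_t = trace$t_ms[starts[runs]] - pad_ms,
             end_t = trace$t_ms[ends[runs]] + pad_ms)
}

overlaps <- function(a0, a1, b0, b1) a0 <= b1 & b0 <= a1

#' Validate a saccade trial
#'
#' Applies the saccade-trial rejection rules: the landing eccentricity
#' (primary-saccade end position minus the fixation point) must be at least
#' `min_amplitude` (3.5 degrees), no blink may overlap the primary saccade,
#' and no saccade may start before fixation-point offset. The primary
#' saccade is the first detected event with onset at or after
#' `fp_off_t`; if there is none the trial is rejected with reason
#' `no_presaccade`.
#'
#' @param trial one-row data.frame (or list) with at least `fp_off_t` and
#'   `fp_x`.
#' @param events [detect_saccades()] output for the trial's trace.
#' @param blinks [detect_blinks()] output for the trial's trace.
#' @param min_amplitude minimum landing eccentricity, deg.
#' @return list with `valid`, `reasons` (character vector), `primary`
#'   (one-row event data.frame or NULL), `amplitude` (landing eccentricity
#'   from the fixation point, deg, NA when no primary saccade).
#' @export
validate_saccade_trial <- function(trial, events, blinks = NULL,
                                   min_amplitude = 3.5) {
  reasons <- character(0)
  prim <- NULL
  amplitude <- NA_real_
  if (nrow(events) > 0 && any(events$onset_t < trial$fp_off_t))
    reasons <- c(reasons, "anticipatory_saccade")
  post <- events[events$onset_t >= trial$fp_off_t, , drop = FALSE]
  if (nrow(post) == 0) {
    reasons <- c(reasons, "no_presaccade")
  } else {
    prim <- post[1, , drop = FALSE]
    amplitude <- prim$end_x - trial$fp_x
    if (amplitude < min_amplitude)
      reasons <- c(reasons, "amplitude_below_3.5")
    if (!is.null(blinks) && nrow(blinks) > 0 &&
        any(overlaps(prim$onset_t, prim$offset_t,
                     blinks$start_t, blinks$end_t)))
      reasons <- c(reasons, "blink_at_saccade")
  }
  list(valid = length(reasons) == 0, reasons = reasons,
       primary = prim, amplitude = amplitude)
}

#' Validate a localization-under-fixation trial
#'
#' Rejects the trial when the click eccentricity (click minus fixation
#' point) is below `min_click` or when any gaze sample leaves the invisible
#' fixation window (radius `fix_window_radius` around the fixation point)
#' during the trial.
#'
#' @param trial one-row data.frame with `click_x`, `fp_x`.
#' @param trace the trial's gaze samples.
#' @param min_click minimum click eccentricity, deg.
#' @param fix_window_radius fixation window radius, deg.
#' @return list with `valid`, `reasons`, `amplitude` (click eccentricity).
#' @export
validate_fixation_localization_trial <- function(trial, trace,
                                                 min_click = 3.5,
                                                 fix_window_radius = 2.5) {
  reasons <- character(0)
  ecc <- trial$click_x - trial$fp_x
  if (is.na(ecc) || ecc < min_click)
    reasons <- c(reasons, "click_below_3.5")
  dev <- sqrt((trace$x_deg - trial$fp_x)^2 + trace$y_deg^2)
  if (any(dev > fix_window_radius))
    reasons <- c(reasons, "fixation_break")
  list(valid = length(reasons) == 0, reasons = reasons, amplitude = ecc)
}

#' Validate a post-saccadic localization trial
#'
#' Requires a click eccentricity of at least `min_click`, an actual saccade
#' before the report (gaze must deviate at least `presaccade_radius` from
#' the fixation point at some time during the trial; otherwise
#' `no_presaccade`), and no saccade initiated before the flash is
#' extinguished (`saccade_before_extinction`).
#'
#' @param trial one-row data.frame with `click_x`, `fp_x`, `flash_off_t`.
#' @param events detected saccade events of the trial.
#' @param trace the trial's gaze samples.
#' @param min_click minimum click eccentricity, deg.
#' @param presaccade_radius minimum gaze deviation evidencing a saccade,
#'   deg.
#' @return list with `valid`, `reasons`, `amplitude` (click eccentricity).
#' @export
validate_postsaccadic_localization_trial <- function(trial, events, trace,
                                                     min_click = 3.5,
                                                     presaccade_radius = 2.5) {
  reasons <- character(0)
  ecc <- trial$click_x - trial$fp_x
  if (is.na(ecc) || ecc < min_click)
    reasons <- c(reasons, "click_below_3.5")
  dev <- sqrt((trace$x_deg - trial$fp_x)^2 + trace$y_deg^2)
  if (max(dev) < presaccade_radius)
    reasons <- c(reasons, "no_presaccade")
  if (nrow(events) > 0 && !is.na(trial$flash_off_t) &&
      any(events$onset_t < trial$flash_off_t))
    reasons <- c(reasons, "saccade_before_extinction")
  list(valid = length(reasons) == 0, reasons = reasons, amplitude = ecc)
}

#' Latency of the target displacement relative to saccade onset
#'
#' @param trial one-row data.frame with `displacement_t`.
#' @param primary_event one-row event data.frame (`onset_t`, `offset_t`).
#' @return list with `latency_ms` (NA when no displacement time is
#'   recorded) and `intra_saccadic` (TRUE when the displacement falls
#'   strictly inside the onset-offset interval).
#' @export
displacement_latency <- function(trial, primary_event) {
  if (is.null(primary_event) || is.na(trial$displacement_t))
    return(list(latency_ms = NA_real_, intra_saccadic = NA))
  lat <- trial$displacement_t - primary_event$onset_t
  intra <- trial$displacement_t > primary_event$onset_t &
    trial$displacement_t < primary_event$offset_t
  list(latency_ms = lat, intra_saccadic = intra)
}

#' Preprocess a session: detection plus trial validation
#'
#' Runs velocity computation, saccade and blink detection and the
#' trial-type-specific rejection rules over every trial of a session, and
#' assembles the analysis columns used downstream: per-trial validity with
#' reasons, landing/click eccentricity (`amplitude`), saccade metrics and
#' displacement latency.
#'
#' @param session a `sim_session`, or a list with `trials` and `gaze`
#'   data.frames in the package's tabular layout.
#' @param threshold velocity threshold, deg/s.
#' @param min_duration_ms minimum saccade duration, ms.
#' @param min_amplitude minimum landing/click eccentricity, deg.
#' @param fix_window_radius fixation window radius, deg.
#' @param blink_pad_ms blink padding, ms.
#' @param smooth passed to [compute_velocity()].
#' @return an object of class `preprocessed_session`: list with `trials`
#'   (the trial table plus `valid`, `reasons`, `amplitude`, `onset_t`,
#'   `offset_t`, `duration`, `peak_velocity`, `latency_ms`,
#'   `intra_saccadic`), `events` (per-trial list), `n_valid`, and the
#'   session metadata.
#' @export
preprocess_session <- function(session, threshold = 30, min_duration_ms = 10,
                               min_amplitude = 3.5, fix_window_radius = 2.5,
                               blink_pad_ms = 25, smooth = FALSE) {
  trials <- session$trials
  gaze_by_trial <- split(session$gaze, session$gaze$trial_id)
  n <- nrow(trials)
  valid <- logical(n); reasons <- character(n); amplitude <- rep(NA_real_, n)
  onset <- offset <- durn <- pkv <- lat <- rep(NA_real_, n)
  intra <- rep(NA, n)
  events_list <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- trials[i, , drop = FALSE]
    trace <- gaze_by_trial[[as.character(tr$trial_id)]]
    ev <- detect_saccades(trace, threshold = threshold,
                          min_duration_ms = min_duration_ms)
    events_list[[i]] <- ev
    bl <- detect_blinks(trace, pad_ms = blink_pad_ms)
    if (tr$trial_type == "saccade") {
      v <- validate_saccade_trial(tr, ev, bl, min_amplitude = min_amplitude)
      if (!is.null(v$primary)) {
        onset[i] <- v$primary$onset_t; offset[i] <- v$primary$offset_t
        durn[i] <- v$primary$duration; pkv[i] <- v$primary$peak_velocity
        dl <- displacement_latency(tr, v$primary)
        lat[i] <- dl$latency_ms; intra[i] <- dl$intra_saccadic
      }
    } else if (tr$trial_type == "localization_fixation") {
      v <- validate_fixation_localization_trial(
        tr, trace, min_click = min_amplitude,
        fix_window_radius = fix_window_radius)
    } else {
      v <- validate_postsaccadic_localization_trial(
        tr, ev, trace, min_click = min_amplitude,
        presaccade_radius = fix_window_radius)
    }
    valid[i] <- v$valid
    reasons[i] <- paste(v$reasons, collapse = ";")
    amplitude[i] <- v$amplitude
  }
  trials$valid <- valid
  trials$reasons <- reasons
  trials$amplitude <- amplitude
  trials$onset_t <- onset; trials$offset_t <- offset
  trials$duration <- durn; trials$peak_velocity <- pkv
  trials$latency_ms <- lat; trials$intra_saccadic <- intra
  structure(list(trials = trials, events = events_list,
                 n_valid = sum(valid),
                 condition = session$condition, mode = session$mode,
                 profile = session$profile, config = session$config,
                 participant = session$participant,
                 gaze = session$gaze),
            class = "preprocessed_session")
}

#' @export
print.preprocessed_session <- function(x, ...) {
  cat(sprintf("<preprocessed_session> %d trials, %d valid (%.1f%%)\n",
              nrow(x$trials), x$n_valid, 100 * x$n_valid / nrow(x$trials)))
  rej <- x$trials$reasons[x$trials$reasons != ""]
  if (length(rej) > 0) {
    tab <- sort(table(unlist(strsplit(rej, ";"))), decreasing = TRUE)
    cat("  rejections:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}
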