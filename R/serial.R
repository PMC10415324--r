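## Lag-1 serial dependence of localization on the post-saccadic error.

#' Post-saccadic error of a saccade trial
#'
#' Signed difference between the (displaced) target position and the
#' saccade landing position, `t2_x - end_x`, rightward positive: the error
#' signal available to the oculomotor system after the saccade. When the
#' displaced target position `t2_x` is missing the error is computed
#' against the initial target `t1_x` and flagged.
#'
#' @param trial one-row data.frame with `t2_x` (and `t1_x` as fallback).
#' @param event one-row saccade event with `end_x`.
#' @return list with `error` (deg) and `against_t1` flag.
#' @export
saccade_error <- function(trial, event) {
  target <- trial$t2_x
  against_t1 <- FALSE
  if (is.na(target)) { target <- trial$t1_x; against_t1 <- TRUE }
  list(error = target - event$end_x, against_t1 = against_t1)
}

#' Localization error of a localization trial
#'
#' Perceived minus true target eccentricity:
#' `(click_x - fp_x) - eccentricity`. Negative values are errors in the
#' foveal (leftward) direction.
#'
#' @param trial one-row data.frame with `click_x`, `fp_x`.
#' @param eccentricity true target eccentricity, deg.
#' @return error, deg.
#' @export
localization_error <- function(trial, eccentricity = 13) {
  (trial$click_x - trial$fp_x) - eccentricity
}

#' Build lag-1 error pairs from a preprocessed session
#'
#' Pairs every valid localization trial with the immediately preceding
#' valid saccade trial (the same block: the paradigm alternates
#' saccade/localization strictly). Pairs whose saccade or localization
#' trial was rejected are dropped, as are de-adaptation trials.
#'
#' @param trials the `trials` data.frame of a [preprocess_session()]
#'   result, with a `phase` column (see [label_phases()]) or `phase_true`.
#' @param eccentricity true target eccentricity, deg.
#' @return data.frame with columns `block`, `saccade_error_prev`,
#'   `localization_error`.
#' @export
build_lagged_pairs <- function(trials, eccentricity = 13) {
  phase_col <- if ("phase" %in% names(trials)) "phase" else "phase_true"
  sacc <- trials[trials$trial_type == "saccade" & trials$valid &
                   trials[[phase_col]] != "deadaptation", , drop = FALSE]
  loc <- trials[grepl("^localization", trials$trial_type) & trials$valid &
                  trials[[phase_col]] != "deadaptation", , drop = FALSE]
  if (nrow(sacc) == 0 || nrow(loc) == 0)
    return(data.frame(block = integer(0), saccade_error_prev = numeric(0),
                      localization_error = numeric(0)))
  # landing eccentricity was stored as `amplitude`; reconstruct end_x
  sacc_err <- ifelse(is.na(sacc$t2_x), sacc$t1_x, sacc$t2_x) -
    (sacc$fp_x + sacc$amplitude)
  err_by_block <- setNames(sacc_err, sacc$block)
  prev <- err_by_block[as.character(loc$block)]
  keep <- !is.na(prev)
  data.frame(block = loc$block[keep],
             saccade_error_prev = unname(prev[keep]),
             localization_error = (loc$click_x[keep] - loc$fp_x[keep]) -
               eccentricity)
}

#' Sliding-window binning of error pairs
#'
#' Averages the pairs into `n_bins` overlapping sliding windows, each
#' containing a fraction `frac` of the pairs: window width
#' `w = round(frac * n)`, with `n_bins` window starts evenly spaced (and
#' rounded) over `[1, n - w + 1]` after sorting pairs by the previous
#' saccade error. Overlapping windows are the only reading under which a
#' fixed bin count and a fixed per-bin fraction can both hold; a disjoint
#' quantile-bin mode is provided as an alternative.
#'
#' @param pairs data.frame from [build_lagged_pairs()].
#' @param n_bins number of bins.
#' @param frac fraction of pairs per bin (sliding mode).
#' @param mode `"sliding"` or `"quantile"` (disjoint equal-count bins).
#' @return data.frame with columns `saccade_error_prev`,
#'   `localization_error` (bin means) and `n_in_bin`; attribute `mode`.
#'   With fewer than `n_bins` pairs the pairs are returned unbinned with a
#'   warning.
#' @export
bin_pairs <- function(pairs, n_bins = 24, frac = 1 / 5,
                      mode = c("sliding", "quantile")) {
  mode <- match.arg(mode)
  n <- nrow(pairs)
  if (n < n_bins) {
    warning("fewer pairs than bins; returning unbinned pairs")
    out <- pairs[order(pairs$saccade_error_prev),
                 c("saccade_error_prev", "localization_error")]
    out$n_in_bin <- 1L
    attr(out, "mode") <- "unbinned"
    return(out)
  }
  ord <- order(pairs$saccade_error_prev)
  px <- pairs$saccade_error_prev[ord]
  py <- pairs$localization_error[ord]
  if (mode == "sliding") {
    w <- max(1L, round(frac * n))
    starts <- unique(round(seq(1, n - w + 1, length.out = n_bins)))
    out <- data.frame(
      saccade_error_prev = vapply(starts, function(s) mean(px[s:(s + w - 1)]),
                                  numeric(1)),
      localization_error = vapply(starts, function(s) mean(py[s:(s + w - 1)]),
                                  numeric(1)),
      n_in_bin = w)
  } else {
    idx <- ceiling(seq_along(px) / (n / n_bins))
    out <- data.frame(
      saccade_error_prev = as.numeric(tapply(px, idx, mean)),
      localization_error = as.numeric(tapply(py, idx, mean)),
      n_in_bin = as.integer(table(idx)))
  }
  attr(out, "mode") <- mode
  out
}

#' Serial-dependence slope
#'
#' Ordinary least-squares regression of localization error on the previous
#' trial's post-saccadic error over the binned pairs. A positive slope is
#' an attractive serial effect: positive post-saccadic errors on trial n-1
#' pull the localization on trial n further peripheral.
#'
#' @param binned output of [bin_pairs()] (or raw pairs for an unbinned
#'   regression).
#' @return object of class `serial_result`: list with `slope`,
#'   `intercept`, `n_bins`, `n_pairs_per_bin`, `binned`, `binning_mode`,
#'   `degenerate` (TRUE when the x spread is zero and the slope is
#'   undefined).
#' @export
serial_slope <- function(binned) {
  x <- binned$saccade_error_prev
  y <- binned$localization_error
  if (length(x) < 3) stop("need at least 3 bins")
  if (stats::sd(x) == 0 || !is.finite(stats::sd(x))) {
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          n_bins = length(x),
                          n_pairs_per_bin = binned$n_in_bin[1],
                          binned = binned,
                          binning_mode = attr(binned, "mode") %||% "unknown",
                          degenerate = TRUE),
                     class = "serial_result"))
  }
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                 n_bins = length(x),
                 n_pairs_per_bin = binned$n_in_bin[1],
                 binned = binned,
                 binning_mode = attr(binned, "mode") %||% "unknown",
                 degenerate = FALSE),
            class = "serial_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.serial_result <- function(x, ...) {
  if (x$degenerate) {
    cat("<serial_result> undefined slope (zero spread in previous error)\n")
  } else {
    cat(sprintf(
      "<serial_result> slope %+.3f, intercept %+.3f (%d bins, %s binning)\n",
      x$slope, x$intercept, x$n_bins, x$binning_mode))
  }
  invisible(x)
}
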