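## Phase labeling, adaptation magnitudes, exponential time-course fits.

#' Label session phases on the valid trials
#'
#' The first `n_baseline` valid trials are labeled `baseline`, the last
#' `n_deadapt` valid trials `deadaptation`, and everything in between
#' `adaptation`. De-adaptation trials only wash out the induced shift and
#' are excluded from all downstream statistics. Counting is by valid-trial
#' order, not raw presentation order, because rejected trials carry no
#' amplitude.
#'
#' @param n_valid number of valid trials in session order, or a vector
#'   whose length is used.
#' @param n_baseline number of baseline trials.
#' @param n_deadapt number of de-adaptation trials.
#' @return character vector of phase labels, or NULL (with a warning) when
#'   the session is unanalyzable (fewer than `n_baseline + n_deadapt + 4`
#'   valid trials).
#' @export
#' @examples
#' table(label_phases(120))  # 20 baseline / 80 adaptation / 20 deadaptation
label_phases <- function(n_valid, n_baseline = 20, n_deadapt = 20) {
  n <- if (length(n_valid) > 1) length(n_valid) else n_valid
  if (n < n_baseline + n_deadapt + 4) {
    warning(sprintf(
      "session unanalyzable: %d valid trials < %d required", n,
      n_baseline + n_deadapt + 4))
    return(NULL)
  }
  n_adapt <- n - n_baseline - n_deadapt
  if (n_adapt < 20)
    warning(sprintf("only %d adaptation trials after phase labeling", n_adapt))
  c(rep("baseline", n_baseline), rep("adaptation", n_adapt),
    rep("deadaptation", n_deadapt))
}

#' Adaptation magnitude: end of adaptation minus baseline
#'
#' The mean of the last `n_window` adaptation-phase amplitudes minus the
#' mean of the first `n_window` baseline amplitudes. Applied identically to
#' saccade amplitudes (landing eccentricity) and to localization amplitudes
#' (click eccentricity). Positive values are shifts in the outward
#' (rightward) direction.
#'
#' @param amplitudes numeric vector of per-trial amplitudes (deg) in valid
#'   trial order.
#' @param phases matching phase labels from [label_phases()].
#' @param n_window window length at each end (default 20 trials).
#' @return list of class `adaptation_result` with `magnitude`,
#'   `baseline_mean`, `end_mean`, `n_baseline_used`, `n_end_used`.
#' @export
adaptation_magnitude <- function(amplitudes, phases, n_window = 20) {
  stopifnot(length(amplitudes) == length(phases))
  base <- amplitudes[phases == "baseline"]
  adapt <- amplitudes[phases == "adaptation"]
  if (length(adapt) < n_window)
    warning(sprintf("only %d adaptation trials; using all of them",
                    length(adapt)))
  if (length(base) == 0 || length(adapt) == 0)
    stop("need baseline and adaptation trials")
  b <- utils::head(base, n_window)
  e <- utils::tail(adapt, n_window)
  structure(list(magnitude = mean(e) - mean(b),
                 baseline_mean = mean(b), end_mean = mean(e),
                 n_baseline_used = length(b), n_end_used = length(e)),
            class = "adaptation_result")
}

#' @export
print.adaptation_result <- function(x, ...) {
  cat(sprintf(
    "<adaptation_result> magnitude %+.3f deg (baseline %.3f -> end %.3f)\n",
    x$magnitude, x$baseline_mean, x$end_mean))
  invisible(x)
}

#' Fit the exponential adaptation time course
#'
#' Nonlinear least squares fit of `y = y0 + A * exp(R0 * x)` over trial
#' index `x`, the model used to describe the growth or decay of saccade and
#' localization amplitudes across adaptation. The sign of `R0` is
#' unconstrained (positive for amplitudes lengthening, negative for
#' shortening). The surface is multi-modal in `(A, R0)`, so the fit is
#' started from a small data-driven grid: `y0` at the mean of the last 10
#' points, `R0` over a grid of signed rates, `A` from the first-point
#' residual back-projected through each candidate rate; the best converged
#' fit by residual sum of squares wins. Non-convergence from every start is
#' reported in the result, never silently.
#'
#' @param x numeric trial indices (strictly increasing).
#' @param y amplitudes, deg.
#' @param rate_grid candidate starting rates for `R0`.
#' @param lower,upper optional parameter bounds `c(y0, A, R0)` passed to
#'   the optimizer (unconstrained by default).
#' @return object of class `exp_fit`: list with `y0`, `A`, `R0`, `rss`,
#'   `n_points`, `fitted`, `converged`, `message`.
#' @export
#' @examples
#' x <- 21:100
#' f <- fit_exponential(x, 13.2 + 0.06 * exp(0.03 * x))
#' c(f$y0, f$A, f$R0)
fit_exponential <- function(x, y,
                            rate_grid = c(-0.1, -0.05, -0.02, -0.01, -0.005,
                                          0.005, 0.01, 0.02, 0.05, 0.1),
                            lower = NULL, upper = NULL) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4) stop("fit_exponential requires at least 4 points")
  if (any(diff(x) <= 0)) stop("x must be strictly increasing")
  # flat data: the exponential term is unidentified; report the offset
  if (stats::sd(y) < 1e-12) {
    return(structure(list(y0 = mean(y), A = 0, R0 = 0, rss = 0,
                          n_points = length(x), fitted = rep(mean(y),
                                                             length(x)),
                          converged = TRUE, message = "flat data"),
                     class = "exp_fit"))
  }
  y0_start <- mean(utils::tail(y, 10))
  best <- NULL
  msgs <- character(0)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 200)
  for (r0 in rate_grid) {
    a0 <- (y[1] - y0_start) * exp(-r0 * x[1])
    if (!is.finite(a0)) next
    start <- list(y0 = y0_start, A = a0, R0 = r0)
    fit <- tryCatch(
      if (is.null(lower)) {
        minpack.lm::nlsLM(y ~ y0 + A * exp(R0 * x), start = start,
                          control = ctrl)
      } else {
        minpack.lm::nlsLM(y ~ y0 + A * exp(R0 * x), start = start,
                          lower = lower, upper = upper, control = ctrl)
      },
      error = function(e) e)
    if (inherits(fit, "error")) { msgs <- c(msgs, conditionMessage(fit)); next }
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      co <- stats::coef(fit)
      best <- list(y0 = unname(co["y0"]), A = unname(co["A"]),
                   R0 = unname(co["R0"]), rss = rss,
                   fitted = stats::fitted(fit))
    }
  }
  if (is.null(best)) {
    return(structure(list(y0 = NA_real_, A = NA_real_, R0 = NA_real_,
                          rss = NA_real_, n_points = length(x),
                          fitted = NULL, converged = FALSE,
                          message = paste(unique(msgs), collapse = " | ")),
                     class = "exp_fit"))
  }
  structure(c(best, list(n_points = length(x), converged = TRUE,
                         message = "")),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<exp_fit> NOT CONVERGED:", x$message, "\n")
  } else {
    cat(sprintf("<exp_fit> y = %.4g %+.4g * exp(%+.4g x)  (rss %.4g, n %d)\n",
                x$y0, x$A, x$R0, x$rss, x$n_points))
  }
  invisible(x)
}

#' Evaluate an exponential fit
#'
#' @param object an `exp_fit`.
#' @param newdata optional data.frame or numeric vector of x values.
#' @param ... unused.
#' @return fitted values `y0 + A * exp(R0 * x)`.
#' @export
predict.exp_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  x <- if (is.data.frame(newdata)) newdata$x else newdata
  object$y0 + object$A * exp(object$R0 * x)
}
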