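## t tests, correlations and default-prior JZS Bayes factors (log10 units).

#' JZS Bayes factor from a t statistic
#'
#' Default Bayes factor for t designs: a Cauchy prior with scale
#' `prior_scale` (default sqrt(2)/2) on the standardized effect size under
#' the alternative, against a point null. Computed by numerical integration
#' of the marginal likelihood in the Zellner-Siow (inverse-gamma mixture)
#' representation: with effective sample size `N` (`n` one-sample,
#' `n1 n2 / (n1 + n2)` two-sample) and degrees of freedom `nu`,
#'
#' `BF10 = [ integral (1+Ng)^(-1/2) (1 + t^2/((1+Ng) nu))^(-(nu+1)/2)
#'           InvGamma(g; 1/2, prior_scale^2/2) dg ] /
#'         (1 + t^2/nu)^(-(nu+1)/2)`.
#'
#' The returned value is `log10(BF10)`; positive values favor the
#' alternative, negative the null.
#'
#' @param t observed t statistic.
#' @param n1 sample size (first group, or the sample for one-sample).
#' @param n2 second-group size (two-sample design only).
#' @param design `"two_sample"` or `"one_sample"`; inferred from `n2` when
#'   missing.
#' @param prior_scale Cauchy prior scale on effect size.
#' @return `log10(BF10)`, a single number.
#' @export
#' @examples
#' jzs_bf_from_t(3.14, 15, 13)   # about 1.0: substantial evidence
#' jzs_bf_from_t(0, 15, 13)      # negative: null favored
jzs_bf_from_t <- function(t, n1, n2 = NULL,
                          design = c("two_sample", "one_sample"),
                          prior_scale = sqrt(2) / 2) {
  if (missing(design)) design <- if (is.null(n2)) "one_sample" else "two_sample"
  design <- match.arg(design)
  if (!is.finite(t)) stop("t must be finite")
  if (design == "two_sample") {
    if (is.null(n2)) stop("two_sample design requires n2")
    if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2")
    n_eff <- n1 * n2 / (n1 + n2)
    nu <- n1 + n2 - 2
  } else {
    if (n1 < 2) stop("sample size must be >= 2")
    n_eff <- n1
    nu <- n1 - 1
  }
  r2 <- prior_scale^2
  integrand <- function(g) {
    (1 + n_eff * g)^(-0.5) *
      (1 + t^2 / ((1 + n_eff * g) * nu))^(-(nu + 1) / 2) *
      (r2 / 2)^(0.5) / gamma(0.5) * g^(-1.5) * exp(-r2 / (2 * g))
  }
  num <- tryCatch(
    stats::integrate(integrand, 0, Inf, rel.tol = 1e-10,
                     subdivisions = 500L),
    error = function(e) e)
  if (inherits(num, "error") || num$message != "OK")
    stop("JZS integration failed: ",
         if (inherits(num, "error")) conditionMessage(num) else num$message)
  den <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  log10(num$value) - log10(den)
}

#' Evidence band of a log10 Bayes factor
#'
#' Absolute-value banding with half-open intervals: anecdotal \[0, 0.5),
#' substantial \[0.5, 1), strong \[1, 1.5), very strong \[1.5, Inf). The
#' sign of the Bayes factor says which hypothesis the evidence favors; the
#' band describes only its strength.
#'
#' @param log10_bf signed log10 Bayes factor.
#' @return character label.
#' @export
bf_band <- function(log10_bf) {
  if (!is.finite(log10_bf)) stop("log10_bf must be finite")
  a <- abs(log10_bf)
  if (a < 0.5) "anecdotal" else if (a < 1) "substantial"
  else if (a < 1.5) "strong" else "very strong"
}

ttest_result <- function(t, df, p, log10_bf, n1, n2 = NA_integer_,
                         design, estimate) {
  structure(list(t = t, df = df, p = p, log10_bf = log10_bf,
                 band = bf_band(log10_bf),
                 direction = sign(estimate), estimate = estimate,
                 n1 = n1, n2 = n2, design = design),
            class = "bf_t_test")
}

#' Two-sample Student t test with JZS Bayes factor
#'
#' Pooled-variance (not Welch) two-sample t test, `df = n1 + n2 - 2`,
#' two-sided p, complemented with the default JZS Bayes factor in log10
#' units. With zero pooled variance and equal means the statistic is 0;
#' with zero pooled variance and unequal means the comparison is flagged
#' degenerate.
#'
#' @param group_a,group_b numeric samples (each n >= 2).
#' @param prior_scale Cauchy prior scale for the Bayes factor.
#' @return object of class `bf_t_test`: `t`, `df`, `p`, `log10_bf`,
#'   `band`, `direction`, `estimate` (mean difference a - b), `n1`, `n2`.
#' @export
t_test_two_sample <- function(group_a, group_b, prior_scale = sqrt(2) / 2) {
  a <- group_a[is.finite(group_a)]; b <- group_b[is.finite(group_b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 observations")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / df
  diff <- mean(a) - mean(b)
  if (sp2 == 0) {
    if (diff == 0) {
      return(ttest_result(0, df, 1, jzs_bf_from_t(0, n1, n2,
                                                  prior_scale = prior_scale),
                          n1, n2, "two_sample", 0))
    }
    stop("degenerate comparison: zero pooled variance with unequal means")
  }
  t <- diff / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(t), df)
  ttest_result(t, df, p,
               jzs_bf_from_t(t, n1, n2, prior_scale = prior_scale),
               n1, n2, "two_sample", diff)
}

#' One-sample Student t test with JZS Bayes factor
#'
#' @param x numeric sample (n >= 2).
#' @param mu null value.
#' @param prior_scale Cauchy prior scale for the Bayes factor.
#' @return object of class `bf_t_test`.
#' @export
t_test_one_sample <- function(x, mu = 0, prior_scale = sqrt(2) / 2) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2) stop("need at least 2 observations")
  s <- stats::sd(x)
  if (s == 0) {
    if (mean(x) == mu) {
      return(ttest_result(0, n - 1, 1,
                          jzs_bf_from_t(0, n, design = "one_sample",
                                        prior_scale = prior_scale),
                          n, NA_integer_, "one_sample", 0))
    }
    stop("degenerate comparison: zero variance away from mu")
  }
  t <- (mean(x) - mu) / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(t), n - 1)
  ttest_result(t, n - 1, p,
               jzs_bf_from_t(t, n, design = "one_sample",
                             prior_scale = prior_scale),
               n, NA_integer_, "one_sample", mean(x) - mu)
}

#' @export
print.bf_t_test <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, p = %.4g, log10BF = %.2f (%s)\n",
              x$df, x$t, x$p, x$log10_bf, x$band))
  invisible(x)
}

#' Pearson correlation with a Bayes factor
#'
#' Pearson r with the usual two-sided p from the t transform. The Bayes
#' factor integrates the Fisher-z likelihood `atanh(r) ~ N(atanh(rho),
#' 1/(n-3))` over a uniform prior on rho in (-1, 1) against the point null
#' rho = 0 — an approximation to the exact default correlation Bayes
#' factor that is adequate away from |r| near 1.
#'
#' @param x,y numeric vectors (n >= 3, nonzero variance).
#' @return object of class `bf_correlation`: `r`, `n`, `p`, `log10_bf`,
#'   `band`.
#' @export
pearson_correlation <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate input: zero variance")
  r <- stats::cor(x, y)
  if (abs(r) < 1) {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), n - 2)
  } else {
    p <- 0
  }
  log10_bf <- if (n > 3 && abs(r) < 1) {
    z <- atanh(r); se <- 1 / sqrt(n - 3)
    num <- stats::integrate(function(rho)
      stats::dnorm(z, atanh(rho), se) * 0.5, -1 + 1e-12, 1 - 1e-12,
      rel.tol = 1e-8)$value
    log10(num) - log10(stats::dnorm(z, 0, se))
  } else NA_real_
  structure(list(r = r, n = n, p = p, log10_bf = log10_bf,
                 band = if (is.finite(log10_bf)) bf_band(log10_bf)
                        else NA_character_),
            class = "bf_correlation")
}

#' @export
print.bf_correlation <- function(x, ...) {
  cat(sprintf("r = %.3f (n = %d), p = %.4g, log10BF = %.2f\n",
              x$r, x$n, x$p, x$log10_bf))
  invisible(x)
}
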