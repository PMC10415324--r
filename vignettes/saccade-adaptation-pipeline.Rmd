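---
title: "Methods: saccade adaptation analysis with a synthetic oculomotor generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: saccade adaptation analysis with a synthetic oculomotor generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saccadapt)
```

## Scope and design

This package reimplements the analysis chain of a double-step saccade
adaptation experiment — detection, trial filtering, adaptation magnitudes,
exponential time-course fits, fixation-stability (BCEA) statistics, lag-1
serial dependence, AQ scoring, and Bayes-factor group inference — and
couples it to a synthetic session generator with known ground truth. The
generator is first-class, tested code: because every latent quantity
(adaptation state, post-saccadic error, serial coupling) is known by
construction, each analysis stage can be validated by parameter recovery
rather than by eyeballing real recordings.

The package uses plain data frames and S3 classes. Central objects:
`generator_config` (paradigm geometry and noise), `participant_profile`
(latent learning parameters), `sim_session` (trial table + 1 kHz gaze
samples + ground truth), `preprocessed_session` (validated trials and
events), and small result classes (`exp_fit`, `adaptation_result`,
`bcea_result`, `serial_result`, `bf_t_test`).

## The paradigm encoded in the generator

A session alternates saccade and localization trials. In a saccade trial,
fixation sits 6.5° left of screen center and the target appears 6.5° right
(a 13° saccade vector). During the first 20 (baseline) and last 20
(de-adaptation) trials the target stays put; during the 80 adaptation
trials it is displaced +3° (outward) or −3° (inward) once the eye velocity
crosses 30 °/s, with a uniform 22 ± 2 ms delivery latency after that
crossing — matching reported mean latencies near 22 ms and guaranteeing
intra-saccadic delivery for the amplitudes in play. Each saccade trial is
followed by a localization trial: a 24 ms flash at the 13° eccentricity,
reported by mouse click while fixating (experiment 1) or after saccading to
the remembered flash (experiment 2).

### Learning model

Oculomotor learning is a single-state delta rule with retention,

$$g_{n+1} = \lambda\, g_n + \alpha\, e_n,$$

where $e_n$ is the post-saccadic error (displaced target minus landing).
Under a constant displacement $D$ it has the closed-form asymptote
$g^\* = \alpha D / (1 - \lambda + \alpha)$. A single state was chosen over a
two-rate model deliberately: it is the minimal model producing partial,
incomplete adaptation while keeping a closed-form fixed point that the
tests can check exactly. Defaults $\alpha = 0.15$, $\lambda = 0.98$ give
$g^\* \approx 2.65°$ of a 3° step. The washout during de-adaptation falls
out of the same rule (errors then pull $g$ back toward zero).

Localization responses decompose generatively as

* under fixation: $\text{click} = 13° + \kappa g_n + \gamma e_{n-1} +
  \varepsilon$, with transfer ratio $\kappa$ (default 0.7) and lag-1 serial
  coupling $\gamma$;
* post-saccadic (experiment 2): $\text{click} = 13° + p_n + \varepsilon$,
  where the perceptual map $p_n$ follows the same update rule with its own
  rate $\alpha_p$ (default 0.1), independent of $\alpha$. This dissociation
  is what lets a participant whose motor map never adapts
  ($\alpha = 0$) still mislocalize in the displacement direction.

The default trait mapping makes $\alpha$ (outward) and $\gamma$ decline
linearly to zero across the sampled AQ range while inward $\alpha$ is
constant — the generative stand-in for the outward-specific trait effect
the pipeline is meant to recover. None of these dynamics are claimed to be
mechanistic truth; they are the simplest generators of the statistical
structure the analysis assumes, calibrated only to printed summary
statistics (saccade durations, displacement latencies, the sign and order
of adaptation magnitudes).

### Kinematics

Saccades use a raised-sine velocity profile
$v(t) = \frac{\pi A}{2D}\sin(\pi t / D)$ with a main-sequence duration law
$D = 20\,\text{ms} + 1.7\,\text{ms/deg} \cdot A$ (≈ 42 ms at 13°,
compatible with reported ~45 ms durations). This profile was chosen
because it integrates exactly to the amplitude and its threshold crossings
invert analytically:
$t^\* = (D/\pi)\,\mathrm{asin}\!\left(\frac{2\theta D}{\pi A}\right)$ for
threshold $\theta$. The detector oracle in the tests is this closed form —
fully independent of the detection code.

### What the generator does not emulate

Within-trial oculometric noise (tremor, drift, microsaccades) is absent:
fixation scatter is a trial-level bivariate-Gaussian offset, constant
within a trial. Blinks exist only as flagged validity gaps, vertical
saccade dynamics and pupil size are not modeled, and saccade latency is a
truncated Gaussian with no task dependence. Consequently, passing recovery
tests demonstrates correctness of the analysis chain, not robustness to
every artifact of real recordings; with real data the velocity
pre-smoothing option (`compute_velocity(smooth = TRUE)`) and the blink
padding would carry more weight.

## Preprocessing choices

Velocity is computed by central differences on unsmoothed positions
(one-sided at the ends); smoothing is available but off by default so it
cannot silently shift onsets. Saccades span maximal runs of speed above
30 °/s lasting at least 10 ms — the duration floor is not from the source
literature but suppresses noise transients far below any goal-directed
saccade toward a 13° target. Onset/offset times are sample-aligned, but
the boundary *positions* are linearly interpolated to the exact threshold
crossing: at 1 kHz the eye still moves ≈ 0.03° per sample near threshold,
and interpolation keeps amplitude errors below ~0.035° where sample-aligned
positions can err by ~0.07°.

Rejection rules: the "landing position smaller than 3.5°" rule is read as
landing eccentricity relative to the fixation point (in screen-centered
coordinates the rule would reject nothing, since the target sits at
+6.5°). The fixation window is implemented as a 2.5° radius; source
descriptions conflict between "radius" and "diameter", the radius reading
is the default and the value is a parameter (`fix_window_radius`).
Injecting exactly one violation yields exactly that reason — the planted
fixture set (`make_fixtures()`) pins this down trial by trial.

## Analysis choices

**Phases** are counted in valid-trial order (first 20 valid = baseline,
last 20 valid = de-adaptation), since rejected trials carry no amplitude;
figure-style raw-order counting can be emulated upstream if needed.
De-adaptation is excluded from every statistic.

**Exponential fits** of $y = y_0 + A e^{R_0 x}$ are multi-modal in
$(A, R_0)$; the fit therefore starts from a data-driven grid ($y_0$ at the
mean of the last 10 points, signed candidate rates, $A$ back-projected
from the first-point residual) and keeps the best converged
least-squares solution. $y_0$ and $R_0$ are unconstrained (bounds are
exposed as arguments). Flat inputs short-circuit to $A = 0$.
Non-convergence is reported in the result, never silently. Note a
statistical caveat verified in development: under trial noise of ~0.3°
the *curve* is recovered without bias, but the raw $A$ estimate is
right-skewed whenever $x$ starts far from 0 (A extrapolates to trial 0),
so parameter-level comparisons across participants should prefer fitted
values or asymptotes over raw $A$.

**Serial dependence**: "24 bins each containing 1/5 of the trials" is
impossible with disjoint bins; it is implemented as overlapping sliding
windows (24 starts evenly spaced, width $n/5$ after sorting by previous
error), the only reading satisfying both counts. A disjoint quantile mode
and unbinned regression are provided (`bin_pairs(mode=)`); binning with
width 1 reproduces the unbinned slope exactly. Slopes come from an
unweighted OLS on bin means (bins hold equal counts). When interpreting
pipeline slopes, note that under fixation the $\kappa g_n$ transfer term
correlates with recent errors during adaptation and inflates the recovered
slope relative to planted $\gamma$; recovery tests therefore plant
$\kappa = 0$.

**BCEA**: both the as-printed form $2 k \sigma_H \sigma_V (1-\rho)^{0.5}$
and the standard form $2 \pi k \sigma_H \sigma_V (1-\rho^2)^{0.5}$ are
computed; the printed form (which omits $\pi$ and squares nothing under
the root — likely typographical in the source) is the reproduction
default, the standard form is the one whose ellipse actually contains
$1 - e^{-k}$ of the Gaussian mass (68% at $k = 1.14$). BCEA units are
deg²; a "percentage of imaged area" normalization seen in figure captions
is unspecified and deliberately not implemented.

**AQ**: binary scoring (1 when the response agrees, slightly or strongly,
with the item's ASD-characteristic direction), five 10-item subscales from
a packaged key file, clinical flag at ≥ 32. The median split sends ties to
the low group — with 28 participants and a median of 17 this reproduces a
15/13 split. Quartile conventions are configurable
(`aq_quartiles(type=)`). The Jarque–Bera p value uses the asymptotic
chi-square(2) reference by default; a Monte-Carlo null is available
because the asymptotic reference is inaccurate at questionnaire-sized n.

**Bayes factors** follow the default JZS formulation: Cauchy prior, scale
$\sqrt{2}/2$, on standardized effect size, integrated numerically in the
inverse-gamma mixture representation; the test suite cross-checks it
against a second, independent integral representation (noncentral-t over
the Cauchy prior) to 1e-4 and against Monte-Carlo prior draws to 2%. The
two-sample t is pooled-variance (every reported df in this literature is
$n_1 + n_2 - 2$). Banding uses the absolute value with half-open
intervals, with the sign kept separately. The correlation Bayes factor
uses a Fisher-z likelihood with a uniform prior on $\rho$ — an
approximation, clearly weaker than the t-design factor, and not used in
any acceptance-grade comparison because the default correlation prior in
the source analyses is not identifiable from the printed values.

## Problem sizes and determinism

Default study conditions are 28 participants, 120 saccade + 120
localization trials per session, 1 kHz traces. The test suite exercises
full-size single sessions and the complete 28-participant outward cohort
end-to-end; multi-seed recovery suites use compact 46-block sessions (the
same generative structure with fewer adaptation trials), sized so the
whole suite runs in minutes. Every stochastic step flows from explicit
seeds: cohorts derive per-session seeds from the master seed, so any
session is individually reproducible, and fixture serialization is
byte-stable across runs.

## Known limitations

* The generator's learning rate/retention defaults imply a faster
  adaptation time constant (~5 trials) than the slow multi-session drifts
  sometimes seen empirically; recovery conclusions are insensitive to
  this, but fitted $R_0$ magnitudes from synthetic sessions should not be
  compared numerically to published human fits.
* Serial-dependence and transfer couplings are linear and lag-1 only.
* The Fisher-z correlation Bayes factor is approximate (see above).
* BCEA group summaries pool samples across participants when asked to
  mirror pooled-dispersion figures; no hierarchical variance model is
  attempted.
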