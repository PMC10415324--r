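# saccadapt

Analysis pipeline for double-step saccade adaptation experiments, built
around a fully synthetic, ground-truth-known session generator.

## The problem

In the McLaughlin double-step paradigm a participant saccades ~13° to a
peripheral target that is displaced by ±3° while the eye is in flight
(triggered when eye velocity crosses 30 °/s). The resulting post-saccadic
error drives a gradual recalibration of saccade amplitude — outward steps
lengthen saccades, inward steps shorten them — and this motor recalibration
partially transfers to visual localization judgments. Studies of individual
differences (for example, autistic-trait questionnaires and oculomotor
flexibility) analyze such sessions with a standard chain of statistics:

* **Saccade detection** at a 30 °/s velocity threshold on 1 kHz gaze
  samples, with blink handling and trial rejection rules (landing or click
  eccentricity < 3.5°, blinks at the saccade, anticipatory saccades,
  fixation breaks beyond a 2.5° window).
* **Adaptation magnitude**: mean amplitude over the last 20 adaptation
  trials minus the first 20 baseline trials; 20 de-adaptation trials at the
  end are excluded from statistics.
* **Exponential time course** `y = y0 + A * exp(R0 * x)` fitted to the
  adaptation-phase amplitudes by nonlinear least squares.
* **Fixation stability** as the bivariate contour ellipse area,
  `BCEA = 2 k σH σV (1 − ρ)^0.5` at `k = 1.14` (the ellipse then contains
  `1 − e^{−k}` ≈ 68% of gaze samples); the conventional
  `2 π k σH σV (1 − ρ²)^0.5` form is also provided.
* **Serial dependence**: the OLS slope of localization error in trial *n*
  on the post-saccadic error of trial *n − 1*, after sliding-window
  binning (24 bins, each holding 1/5 of the pairs).
* **AQ scoring**: binary scoring of the 50-item Autism-Spectrum Quotient,
  five subscales, median split into low/high trait groups.
* **Inference**: pooled-variance t tests and Pearson correlations
  complemented with default-prior JZS Bayes factors (Cauchy scale
  `sqrt(2)/2`) reported as `log10(BF10)`, banded as anecdotal (0–0.5),
  substantial (0.5–1), strong (1–1.5), very strong (> 1.5).

Real recordings of this paradigm are rarely redistributable, so the package
ships a seeded generator that emulates whole experiments — main-sequence
raised-sine saccades, velocity-contingent displacement ~22 ms after the
detected onset, a single-state learning rule
`g ← λ g + α (post-saccadic error)` with closed-form asymptote
`α D / (1 − λ + α)`, lag-1 error coupling of localization reports, and
bivariate-Gaussian fixation scatter. Every analysis stage is therefore
testable by parameter recovery against known ground truth.

## Worked example

```r
library(saccadapt)

cfg <- pipeline_config(experiment = "exp1_outward", n_participants = 28,
                       seed = 2024)
report <- run_pipeline(cfg)

# trait-magnitude correlation across the cohort
with(report$participants, pearson_correlation(aq, magnitude_saccade))
#> r = -0.847 (n = 28), p = 1.284e-08, log10BF = 7.31

# low vs high AQ group difference in adaptation magnitude
subset(report$group_stats, measure == "magnitude_saccade" & type == "t_test",
       c(statistic, df_or_n, p, log10_bf, band))
#>  statistic df_or_n         p log10_bf        band
#>      4.952      26 3.815e-05    2.675 very strong
```

The simulated cohort maps higher AQ scores to lower oculomotor learning
rates, so the pipeline recovers a strongly negative trait–magnitude
correlation and a large group difference — the generator's planted effect,
measured end-to-end through gaze traces, detection, rejection and
statistics. (The generative effect is noise-free by design, hence cleaner
than any human cohort.)

Individual stages are exposed directly:

```r
s   <- simulate_session(profile_from_trait(12), generator_config(seed = 3),
                        condition = "outward")
pre <- preprocess_session(s)        # detection + rejection rules
pre
#> <preprocessed_session> 240 trials, 240 valid (100.0%)

jzs_bf_from_t(3.14, 15, 13)         # log10 JZS Bayes factor
#> [1] 0.9964873
bcea_from_moments(1, 1, 0, k = 1.14)
#> [1] 2.28
```

## Package layout

| file | contents |
| --- | --- |
| `R/generator-config.R`, `R/simulate.R` | session/cohort generator and learning model |
| `R/preprocess.R` | velocity, saccade/blink detection, rejection rules |
| `R/adaptation.R` | phase labeling, magnitudes, exponential fits |
| `R/bcea.R` | fixation-stability statistics |
| `R/serial.R` | lag-1 serial dependence |
| `R/aq.R` | AQ scoring, median split, Jarque–Bera |
| `R/inference.R` | t tests, correlations, JZS Bayes factors |
| `R/pipeline.R`, `R/io.R` | orchestration, fixtures, delimited-text I/O |

The methods vignette (`vignettes/saccade-adaptation-pipeline.Rmd`)
documents the model assumptions, parameter choices and known limitations.
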