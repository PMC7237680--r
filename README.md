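# blinkengage

Quantifying viewer engagement from spontaneous eye-blink inhibition.

Blinking is suppressed at moments a viewer perceives as important, because
a blink costs visual information. When two groups watch the *same* videos
under different tasks — composite films alternating land-animal and
water-animal scenes every 1–60 s, with half the cohort counting land
animals and half counting water animals — each group blinks less during its
task-relevant scenes. `blinkengage` implements the full analysis pipeline
for this design, for pupillometry/eye-tracking researchers who want to use
blink-rate patterns as an individual-level engagement measure:

- **Blink detection** from pupil traces (occlusion dynamics: rapid diameter
  drop + vertical pupil-center displacement), with track-loss flagging and
  a renderer/detector round-trip validation harness.
- **Rate metrics**: pooled blinks-per-minute (BPM) per session/scene
  category, interval-averaged BPM vectors, smoothed instantaneous group
  rate.
- **Content-aware classification**: ROC analysis on the per-participant
  metric `bpm_land − bpm_water` (land counters sit below zero), with
  trapezoidal AUC, Youden-optimal threshold, and exact Clopper–Pearson
  intervals for sensitivity/specificity.
- **Content-unaware classification**: linear SVM on interval-rate vectors
  predicting attended-scene *parity* (odd vs even scene positions), with
  leave-one-out cross-validation, a nested 75/25 search over
  C = 10⁻²…10¹⁰, and a label-permutation null with the add-one p-value
  `p = (1 + #{null ≥ obs}) / (n_perm + 1)`.
- **Classification strength**: per-condition KDE likelihood ratios
  LR = P(metric | correct group) / P(metric | incorrect group), plus
  linear/quadratic/cubic/exponential regressions of log LR on individual
  blink rate (Bonferroni over 13 conditions) and Deming regression.
- **Group statistics**: Shapiro–Wilk, pooled two-sample *t*, the
  scene-type × group mixed-ANOVA interaction (computed via the exact
  F = t² identity and cross-checked against `aov`), and
  Bonferroni–Holm-corrected per-timescale paired tests.
- A **synthetic cohort generator**: truncated-normal baseline rates
  (moment-matched to mean 12.6, SD 6.7, bounds [2, 26] bpm), task-locked
  suppression (rate λρ in relevant scenes, λ(2−ρ) in irrelevant ones), and
  a dead-time-compensated Poisson blink process, so the whole pipeline is
  testable without hardware.

## Worked example

```r
library(blinkengage)

# simulate the default study: 11 land counters + 10 water counters,
# 13 composite videos (~29.7 min viewing), suppression ratio 0.5
cohort <- simulate_cohort(cohort_params(seed = 11))
cohort
#> <blink_cohort: 21 participants (11 land / 10 water counters), 26 videos, 6598 blinks>

rates <- scene_rates(cohort$participants, cohort$events, cohort$schedules)
all(rates$bpm_relevant < rates$bpm_irrelevant)
#> [1] TRUE

# content-aware: every participant suppresses task-relevant scenes,
# so the signed BPM difference separates the groups perfectly
classify_content_aware(rates$metric, rates$group)
#> <roc_result: AUC = 1.000; at threshold 1.72 sensitivity = 100.0% [71.5, 100.0],
#>  specificity = 100.0% [69.2, 100.0] (n = 11/10)>

# content-unaware: parity prediction from 5 s interval-rate vectors
feats <- build_features(cohort$participants, cohort$events,
                        cohort$schedules, interval_s = 5)
loocv_classify(feats$x, feats$labels, svm_config(), seed = 2)
#> <classifier_report: 20/21 correct (95.24%)>
```

The AUC of 1 and 100% sensitivity/specificity say the signed land−water
rate difference assigns every simulated participant to the correct task
group; the LOOCV report says 20 of 21 participants' attended-scene parity
is recovered without any knowledge of scene timing. The bracketed
percentages are exact 95% binomial intervals on the at-threshold counts.

`run_full(run_config(global_seed = 1))` chains every stage (simulation,
rates, both classifiers, likelihood ratios, statistics) and writes CSVs
plus a JSON manifest. A thin command-line wrapper is included at
`inst/cli/blinkengage`.

## Package layout

| file | contents |
| --- | --- |
| `R/core-types.R`, `R/core-io.R` | domain tables, invariants, CSV readers/writers |
| `R/synthetic.R` | schedules, cohort sampling, blink process, trace renderer |
| `R/detect.R` | down-sampling, blink detector, detection scoring |
| `R/rates.R` | BPM, scene/interval rates, instantaneous rate, features |
| `R/roc.R` | content-aware ROC/AUC, Clopper–Pearson |
| `R/svm.R` | LOOCV linear SVM, nested C search, permutation test |
| `R/strength.R` | KDE likelihood ratios, regression suite, Deming fit |
| `R/stats.R` | Shapiro–Wilk, t tests, interaction ANOVA, Holm |
| `R/pipeline.R` | orchestration, seeds, manifest |

See the vignette (`vignettes/blink-rate-engagement.Rmd`) for the model
assumptions, parameter choices, and known limitations.
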