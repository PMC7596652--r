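---
title: "Methods: construction and evaluation of a wearable-derived frailty score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: construction and evaluation of a wearable-derived frailty score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fifascore)
```

## The problem and the score

Elderly candidates for transcatheter aortic valve replacement are routinely
risk-stratified by surgical scores that ignore frailty, while formal frailty
instruments (Edmonton Frail Scale, 6-minute walk test) require supervised
clinic time. The FIFA score replaces the clinic visit with a week of
free-living wrist-tracker data. Its construction has three stages, each
implemented as an exported function:

1. **Aggregation** (`aggregate_weekly`). A patient's device-days are sorted
   by their ordinal day index; the first and last day are dropped because a
   wear period that starts and ends mid-day produces systematically
   incomplete totals on those two days. Remaining days are averaged per
   parameter, ignoring device gaps. The exclusion is positional, not based
   on calendar completeness flags, because only the ordinal position is
   guaranteed to be available.
2. **Threshold derivation** (`youden_threshold`, wrapped by `fifa_fit`).
   For each of three predefined categories — walking (default parameter:
   daily steps, risk direction negative), heart rate (daily maximum,
   positive) and preprocedural stress (overall daily stress level on the
   device's 0–100 scale, positive) — the cutoff maximising the Youden index
   J = sensitivity + specificity − 1 against in-hospital death is chosen.
3. **Scoring** (`fifa_assign`). One point per category whose weekly mean
   strictly breaches its cutoff in the risk direction. Totals 0/1/2/3 map
   to the stages no / mild / moderate / severe frailty; the binary frailty
   definition is moderate-or-severe.

The score presumes a single underlying frailty construct expressed across
channels; that assumption is mirrored in the simulator (below) as one
latent factor.

## ROC machinery

`auc_rank` estimates the AUC by the Mann–Whitney midrank identity: the
probability that a random case outranks a random control, ties counted ½.
For negatively correlated parameters the predictor is negated first, so
reported AUCs are always in the stated risk direction and AUC(positive) +
AUC(negative) = 1 exactly, including under ties. The empirical ROC curve is
the staircase over all distinct thresholds; its trapezoidal area equals the
rank AUC to machine precision, which the test suite asserts.

The confidence interval uses the Hanley–McNeil standard error with a normal
approximation, clipped to [0, 1]. This is a deliberate, documented choice:
it is a reproducible closed form that behaves sensibly at the ~50-patient
scale this design targets. DeLong's covariance-based variance is available
behind `ci_method = "delong"` and is cross-checked against an independent
implementation (pROC) in the tests. A constant predictor returns AUC 0.5
with a `degenerate` flag rather than an error.

### Cutoff scan and numerical choices

* Candidate cutoffs are the midpoints between consecutive distinct observed
  values plus −∞/+∞ sentinels, so the chosen threshold never coincides with
  an observed value on continuous data and does not depend on coincidences
  of the observed support.
* Breaches are strict (`>` for positive, `<` for negative direction); a
  weekly mean exactly at the cutoff scores no point. On discrete inputs
  this makes the rule predictable; on continuous inputs it is vacuous by
  the midpoint construction.
* The J-maximising candidate is selected on an integer-scaled J
  (sensitivity and specificity kept as counts), so cutoffs with
  mathematically equal J are true ties rather than one-ulp accidents.
  Ties are broken toward higher sensitivity — a frailty screen should
  favour detection — then toward the smaller cutoff.
* Degenerate inputs: no cases or no controls is an error (AUC undefined);
  empty cohorts are errors for prevalence; an empty daily table aggregates
  to an empty profile table without error.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `min_days` | 3 | retained days | keeps short compliance usable; forbids single-day "weekly" profiles |
| `days_per_patient` | 9 | days | one full week retained after the first/last trim |
| category map | steps / hr_max / stress_overall | — | walking, heart rate and stress categories; configurable because the operative walking parameter is under-determined at single-cohort scale |
| `frailty_effect` | 2 | logit per SD of latent frailty | a strong but not deterministic mortality signal |
| `baseline_death_logit` | qlogis(0.06) | logit | 6% in-hospital mortality at average frailty |
| `missing_rate` | 0.02 | probability/cell | occasional device gaps |
| `conf_level` | 0.95 | — | conventional two-sided intervals |

Channel baselines and scales (`fifa_channel_defaults()`) are plausible
elderly-cohort values — 4000 steps/day, maximum heart rate 110 bpm, overall
stress 35/100, 60 min/day in high stress, 600 min/day at rest. Nothing
downstream depends on the specific baselines, only on loadings and effects;
the tests enforce this by operating on loadings.

## What the simulator emulates — and what it does not

`simulate_cohort` draws a scalar latent frailty f ~ N(0, 1) per patient;
each channel's patient-level mean is `baseline + loading × scale × f`,
daily values add independent Gaussian noise, and death is Bernoulli with
logit `baseline_death_logit + frailty_effect × f`. Default loadings follow
the observed correlation directions (stress burden and heart-rate maximum
positive; rest minutes and walking negative; sleep channels zero, since
sleep is not part of the score). Constraints are enforced by construction
or clipping: heart-rate min/max are ordered pairwise, rest minutes are
capped so stress-state minutes fit in a day, total sleep is floored at
deep + light, stress is clipped to [0, 100] and all quantities to ≥ 0.
Clipping after noise (rather than truncated sampling) slightly attenuates
extreme loadings; this is accepted for simplicity and documented here.
Missingness is completely at random.

The simulator deliberately omits circadian and within-day structure,
informative missingness (frailer patients plausibly wear devices less),
inter-channel correlation beyond the single factor, competing risks, and
the device's proprietary HRV-to-stress algorithm (stress values are treated
as given input data). Passing tests therefore demonstrate the statistical
machinery is correct under the stated generative model — not that a real
cohort satisfies that model.

## Study designs used in validation

Problem sizes were chosen as the smallest that make the statistical claims
sharp:

* **Oracle equivalence.** 500 random tied instances (n ≤ 60) against
  exhaustive pairwise enumeration (AUC) and an exhaustive candidate scan
  (Youden), agreement to 1e-12.
* **Null calibration** (`study_null_calibration`). 200 pairs of independent
  50-patient cohorts with `frailty_effect = 0`. Thresholds are fitted on
  one cohort and the score evaluated on the other, because Youden-derived
  cutoffs are optimistically biased on the deriving cohort — three
  data-dredged cutoffs against a handful of deaths cannot average to AUC
  0.5 in-sample under any correct implementation. Out-of-sample, the mean
  AUC must sit within 3 standard errors of 0.5. Replicates whose training
  cohort has no deaths (or test cohort lacks a case or control) are
  skipped and counted.
* **Parameter recovery** (`study_parameter_recovery`). 200 replicates of
  2000 patients in which only the overall stress level carries the latent
  signal (loading +1) beside a weak negative step loading. Two claims per
  replicate: the derived stress cutoff falls inside the central 90% of the
  planted discriminating region, and the composite score's AUC exceeds
  that of every channel not planted to carry signal. The "planted
  discriminating region" is operationalised as the interval of noiseless
  patient-level stress means between the survivor and death class
  centroids (from the simulator's latent table), shrunk 5% per side: any
  useful cutoff must separate the class centres, and the latent table
  makes that region observable. The latent-scale Youden cutoff computed on
  the noiseless means is also recorded as a point oracle; its sampling
  spread is naturally narrower than the profile-derived cutoff's (the
  latter adds daily noise), which is why the region — not the oracle's
  sampling quantiles — defines the acceptance band.

## Design decisions on the comparators

* **EFS bands.** The published bands (0–5 not frail, 6–7 vulnerable, 8–9
  mild, 10–11 moderate, >12 severe) leave 12 unassigned; standard EFS
  practice classes ≥ 12 as severe, which this package adopts for a gapless
  partition of 0–17. Binary frailty is mild-or-worse.
* **Gait-speed bands.** "≥ 0.5 m/s slow" and "> 0.83 m/s normal" leave
  (0.5, 0.83] ambiguous; since the binary frailty definition is "gait
  speed below 0.83 m/s or infeasible test", 0.83 itself is classed slow
  (closed band). The 6MWT duration is fixed at 360 s; inputs are a
  distance or an infeasibility flag. An infeasible test is its own,
  most-frail category.
* **Ordinal ROC codes.** Instruments enter the comparison as ordinal stage
  codes ordered by increasing frailty (so a uniform positive direction
  applies), not as binary flags: a binary flag caps the achievable
  granularity and cannot reproduce multi-level discrimination. No formal
  AUC-difference test is performed; the comparison is descriptive.
* **Prevalence bookkeeping.** On the published stage counts (11/10/21/8 of
  50) the moderate-or-severe fraction is 29/50 = 58%; the source report
  prints 55.5%, which is not reconcilable from its own stage table. The
  package reports the recomputed value.

## Known limitations

The Youden cutoffs are retrospective and single-cohort; applying a fitted
`"fifa"` object to new data (`predict`) is supported precisely so that
external validation is the natural workflow. Hanley–McNeil intervals are
asymptotic and can be anti-conservative with very few events. The walking
category's operative parameter is configurable but defaults to step count
even though its single-parameter discrimination can be weak. Sleep
parameters are screened but never scored. None of the machinery addresses
long-term (e.g. 1-year) mortality, for which the conventional instruments
were designed.
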