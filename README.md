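# fifascore

Frailty is the strongest patient characteristic missing from conventional
cardiac-surgical risk models, yet in practice it is often judged by an
"eyeball test" because formal instruments are slow and resource-hungry.
`fifascore` implements a wearable-based alternative: a week of daily
fitness-tracker summaries (steps, distance, heart-rate extremes,
HRV-derived stress minutes, sleep states) is condensed into a per-patient
weekly profile, data-driven cutoffs are derived for three predefined
categories — walking, heart rate and preprocedural stress — and each
patient receives one point per breached category. The resulting 0–3-point
FItness-tracker assisted Frailty-Assessment (FIFA) score maps to four
stages (no / mild / moderate / severe frailty) and is evaluated head to
head against the Edmonton Frail Scale classification (EFS-C) and the
6-minute-walk-test gait-speed category (GSC-6MWT) as a predictor of
in-hospital mortality.

The package is aimed at biostatisticians and clinical researchers who want
to reproduce, stress-test or extend this style of composite wearable score.

## The statistics at the core

* **Discrimination.** For a predictor *X* and binary outcome *D*, the area
  under the ROC curve is estimated rank-based as
  AUC = P(X<sub>case</sub> > X<sub>control</sub>) + ½·P(tie)
  (Mann–Whitney midrank identity). Confidence intervals use the
  Hanley–McNeil standard error by default, DeLong's variance optionally.
* **Cutoffs.** Each category's threshold maximises the Youden index
  *J* = sensitivity + specificity − 1 over all midpoint cutoffs between
  consecutive distinct values (±∞ sentinels included). Ties in *J* favour
  sensitivity, then the smaller cutoff. Points are awarded on strict
  breaches: value > cutoff for positively correlated categories, value <
  cutoff for negatively correlated ones.
* **Score.** Total points 0/1/2/3 map to no/mild/moderate/severe frailty;
  "frail" in prevalence terms means moderate or severe. Instruments are
  compared by the AUC of their ordinal stage codes.
* **Simulation.** A single latent frailty factor f ~ N(0,1) drives both
  channel means (baseline + loading·scale·f) and mortality
  (logit p = β₀ + β₁·f), so calibration and parameter-recovery claims can
  be tested without patient data.

## Worked example

```r
library(fifascore)

cohort   <- simulate_cohort(cohort_sim_config(n_patients = 60, seed = 42))
profiles <- aggregate_weekly(cohort$daily)   # trims first/last day, averages
fit      <- fifa_fit(profiles, cohort$outcomes)
fit
#> FIFA frailty score fit (60 patients)
#> Category thresholds (Youden-derived):
#>   walking     steps           1 point when < 3888  (J=0.438)
#>   heart_rate  hr_max          1 point when > 111.9  (J=0.625)
#>   stress      stress_overall  1 point when > 38.88  (J=0.625)
#> Stage counts: no_frailty=24, mild_frailty=10, moderate_frailty=14, severe_frailty=12
#> Frailty prevalence (moderate+severe): 43.3%
#> Mortality discrimination: AUC 0.889 (95% CI 0.763-1.000)
```

Reading this: among 60 simulated patients, walking under ~3.9 k steps/day,
a daily heart-rate maximum above ~112 bpm or an overall stress level above
~39/100 each contribute one frailty point; 26/60 patients (43.3%) are
moderately or severely frail, and the ordinal score separates the 12
in-hospital deaths from survivors with AUC 0.889.

The single-parameter screen and the instrument comparison:

```r
head(parameter_screen(profiles, cohort$outcomes), 4)
#>         parameter direction       auc    ci_low   ci_high n_cases n_controls
#> 1 stress_high_min  positive 0.8802083 0.7498116 1.0000000      12         48
#> 2          hr_max  positive 0.8732639 0.7397597 1.0000000      12         48
#> 3  stress_overall  positive 0.8715278 0.7372689 1.0000000      12         48
#> 4 stress_rest_min  negative 0.8506944 0.7080132 0.9933757      12         48

efs  <- efs_classify(rep_len(c(3L, 7L, 9L, 12L), 60), profiles$patient_id)
gait <- gait_classify(rep_len(c(TRUE, TRUE, FALSE), 60),
                      rep_len(c(400, 160, NA), 60), profiles$patient_id)
compare_scores(predict(fit), efs, gait, cohort$outcomes)
#> Frailty instruments vs hospital mortality (12 case(s), 48 control(s))
#>     score   AUC          CI prevalence
#>      fifa 0.889 0.763-1.000      43.3%
#>  gsc_6mwt 0.674 0.491-0.856      66.7%
#>     efs_c 0.474 0.292-0.656      50.0%
```

A command-line wrapper over the same functions lives at
`inst/cli/fifa.R` (`simulate`, `thresholds`, `score`, `compare`).
See `vignettes/fifa-methods.Rmd` for the modelling assumptions, tuning
parameters and limitations.

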