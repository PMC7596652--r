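test_that("parameter screen rows match direct ROC calls and sort by AUC", {
  co <- simulate_cohort(cohort_sim_config(n_patients = 100, seed = 19,
                                          missing_rate = 0))
  prof <- aggregate_weekly(co$daily)
  scr <- parameter_screen(prof, co$outcomes)
  expect_setequal(scr$parameter, fifa_parameters())
  expect_true(all(diff(scr$auc) <= 0))
  y <- co$outcomes$hospital_death[match(prof$patient_id,
                                        co$outcomes$patient_id)]
  direct <- auc_rank(prof$stress_overall, y, "positive")
  row <- scr[scr$parameter == "stress_overall", ]
  expect_equal(row$auc, direct$auc)
  expect_equal(row$ci_low, direct$ci_low)
  expect_equal(row$n_cases + row$n_controls, nrow(prof))
})

test_that("a planted stress effect outranks the walking channels", {
  cfg <- cohort_sim_config(
    n_patients = 1200, seed = 33, frailty_effect = 2, missing_rate = 0,
    channel_loadings = c(stress_overall = 1, steps = -0.2,
                         distance_km = -0.2, hr_min = 0, hr_max = 0,
                         stress_high_min = 0, stress_rest_min = 0))
  co <- simulate_cohort(cfg)
  prof <- aggregate_weekly(co$daily)
  scr <- parameter_screen(prof, co$outcomes)
  rank_of <- function(p) which(scr$parameter == p)
  expect_lt(rank_of("stress_overall"), rank_of("steps"))
  expect_lt(rank_of("stress_overall"), rank_of("distance_km"))
})

test_that("score comparison reproduces the observed-cohort headline", {
  obs <- observed_cohort()
  fifa_scores <- data.frame(patient_id = obs$patient_id, total = obs$total,
                            frail_binary = obs$total >= 2)
  # comparators constructed as arbitrary frail/not-frail fillers: the FIFA
  # row must not depend on them
  efs <- efs_classify(rep(c(3, 9), 25), obs$patient_id)
  gait <- gait_classify(rep(TRUE, 50), rep(c(400, 100), 25),
                        obs$patient_id)
  outc <- data.frame(patient_id = obs$patient_id,
                     hospital_death = obs$hospital_death)
  cmp <- compare_scores(fifa_scores, efs, gait, outc)
  fifa_row <- cmp[cmp$score == "fifa", ]
  expect_equal(fifa_row$auc, 119 / 141, tolerance = 1e-12)
  expect_equal(round(fifa_row$auc, 3), 0.844)
  expect_equal(fifa_row$prevalence, 29 / 50)
  # internal consistency with a direct rank AUC on the ordinal totals
  expect_equal(fifa_row$auc,
               auc_rank(obs$total, obs$hospital_death)$auc)
})

test_that("comparison joins safely and ignores row order", {
  obs <- observed_cohort()
  fifa_scores <- data.frame(patient_id = obs$patient_id, total = obs$total,
                            frail_binary = obs$total >= 2)
  efs <- efs_classify(sample(0:17, 50, replace = TRUE), obs$patient_id)
  gait <- gait_classify(rep(TRUE, 50), seq(50, 540, length.out = 50),
                        obs$patient_id)
  outc <- data.frame(patient_id = obs$patient_id,
                     hospital_death = obs$hospital_death)
  cmp <- compare_scores(fifa_scores, efs, gait, outc)
  expect_true(all(cmp$n_cases + cmp$n_controls == 50))
  reordered <- compare_scores(fifa_scores[sample(50), ], efs[sample(50), ],
                              gait[sample(50), ], outc[sample(50), ])
  expect_equal(reordered, cmp)
  # mismatched ids are dropped with a report, empty intersection errors
  expect_warning(sub <- compare_scores(fifa_scores[1:45, ], efs, gait, outc),
                 "dropped")
  expect_true(all(sub$n_cases + sub$n_controls == 45))
  efs_other <- efs_classify(1:5, paste0("X", 1:5))
  expect_error(compare_scores(fifa_scores, efs_other, gait, outc),
               "no patients")
})

test_that("constant instruments fall to chance discrimination", {
  obs <- observed_cohort()
  fifa_scores <- data.frame(patient_id = obs$patient_id, total = rep(1, 50),
                            frail_binary = rep(FALSE, 50))
  efs <- efs_classify(rep(6, 50), obs$patient_id)
  gait <- gait_classify(rep(TRUE, 50), rep(200, 50), obs$patient_id)
  outc <- data.frame(patient_id = obs$patient_id,
                     hospital_death = obs$hospital_death)
  cmp <- compare_scores(fifa_scores, efs, gait, outc)
  expect_equal(cmp$auc, rep(0.5, 3))
})

test_that("report rendering lists every section and row", {
  obs <- observed_cohort()
  fifa_scores <- data.frame(patient_id = obs$patient_id, total = obs$total,
                            frail_binary = obs$total >= 2)
  efs <- efs_classify(rep(c(3, 9), 25), obs$patient_id)
  gait <- gait_classify(rep(TRUE, 50), rep(c(400, 100), 25), obs$patient_id)
  outc <- data.frame(patient_id = obs$patient_id,
                     hospital_death = obs$hospital_death)
  cmp <- compare_scores(fifa_scores, efs, gait, outc)
  lines <- capture.output(out <- render_roc_report(list(scores = cmp)))
  expect_true(any(grepl("fifa", lines)))
  expect_true(any(grepl("AUC 0.844", lines)))
})
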