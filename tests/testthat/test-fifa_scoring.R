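# a minimal profile table with just the scored columns
score_profiles <- function(steps, hr_max, stress) {
  n <- length(steps)
  data.frame(patient_id = sprintf("S%02d", seq_len(n)),
             steps = steps, hr_max = hr_max, stress_overall = stress,
             stringsAsFactors = FALSE)
}

fixed_thresholds <- function(steps_cut = 3000, hr_cut = 115,
                             stress_cut = 40) {
  list(walking = structure(list(parameter = "steps",
                                direction = "negative",
                                cutoff = steps_cut),
                           class = "threshold_spec"),
       heart_rate = structure(list(parameter = "hr_max",
                                   direction = "positive",
                                   cutoff = hr_cut),
                              class = "threshold_spec"),
       stress = structure(list(parameter = "stress_overall",
                               direction = "positive",
                               cutoff = stress_cut),
                          class = "threshold_spec"))
}

test_that("points, stages and the frailty flag follow the fixed mapping", {
  prof <- score_profiles(steps = c(5000, 1000, 1000, 1000),
                         hr_max = c(100, 100, 130, 130),
                         stress = c(20, 20, 20, 80))
  sc <- fifa_assign(prof, fixed_thresholds())
  expect_equal(sc$total, c(0, 1, 2, 3))
  expect_equal(as.character(sc$stage),
               c("no_frailty", "mild_frailty", "moderate_frailty",
                 "severe_frailty"))
  expect_equal(sc$frail_binary, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(sc$point_walking + sc$point_heart_rate + sc$point_stress,
               sc$total)
})

test_that("a value exactly at the cutoff scores no point in either direction", {
  prof <- score_profiles(steps = 3000, hr_max = 115, stress = 40)
  sc <- fifa_assign(prof, fixed_thresholds())
  expect_equal(sc$total, 0)
  # one-line rule oracle: strict breach only
  v <- c(at = 115, above = 115.01, below = 114.99)
  expect_equal(as.integer(v > 115), c(0L, 1L, 0L))
})

test_that("missing configured values raise a scoring error naming the patient", {
  prof <- score_profiles(steps = c(1000, NA), hr_max = c(100, 100),
                         stress = c(10, 10))
  expect_error(fifa_assign(prof, fixed_thresholds()), "steps.*S02")
  prof2 <- score_profiles(steps = 1, hr_max = 1, stress = 1)
  prof2$hr_max <- NULL
  expect_error(fifa_assign(prof2, fixed_thresholds()), "hr_max")
})

test_that("worsening any single category never lowers the score", {
  set.seed(77)
  th <- fixed_thresholds()
  for (i in 1:50) {
    prof <- score_profiles(steps = runif(1, 0, 6000),
                           hr_max = runif(1, 80, 140),
                           stress = runif(1, 0, 100))
    base <- fifa_assign(prof, th)$total
    worse <- prof
    pick <- sample(3, 1)
    if (pick == 1) worse$steps <- worse$steps - runif(1, 0, 2000)
    if (pick == 2) worse$hr_max <- worse$hr_max + runif(1, 0, 30)
    if (pick == 3) worse$stress_overall <-
        min(100, worse$stress_overall + runif(1, 0, 40))
    expect_gte(fifa_assign(worse, th)$total, base)
  }
})

test_that("stages partition the cohort and scoring ignores patient order", {
  co <- simulate_cohort(cohort_sim_config(n_patients = 40, seed = 14))
  prof <- aggregate_weekly(co$daily)
  fit <- fifa_fit(prof, co$outcomes)
  sc <- fit$scores
  expect_equal(sum(table(sc$stage)), nrow(sc))
  expect_true(all(sc$total %in% 0:3))
  shuffled <- prof[sample(nrow(prof)), ]
  sc2 <- predict(fit, shuffled)
  expect_equal(sc2[order(sc2$patient_id), ]$total,
               sc[order(sc$patient_id), ]$total)
})

test_that("prevalence equals a direct count and rejects empty cohorts", {
  prof <- score_profiles(steps = c(1, 1, 9999), hr_max = c(130, 90, 90),
                         stress = c(90, 90, 10))
  sc <- fifa_assign(prof, fixed_thresholds())
  expect_equal(fifa_prevalence(sc), mean(sc$total >= 2))
  all_severe <- fifa_assign(score_profiles(1, 130, 90), fixed_thresholds())
  expect_equal(fifa_prevalence(all_severe), 1)
  mildest <- fifa_assign(score_profiles(9999, 90, 10), fixed_thresholds())
  expect_equal(fifa_prevalence(mildest), 0)
  expect_error(fifa_prevalence(sc[0, ]), "empty")
})

test_that("perfectly separated cohorts give J = 1 per category and AUC 1", {
  n <- 20
  death <- rep(c(FALSE, TRUE), c(15, 5))
  prof <- score_profiles(steps = ifelse(death, 500, 5000),
                         hr_max = ifelse(death, 130, 100),
                         stress = ifelse(death, 80, 20))
  fit <- fifa_fit(prof, data.frame(patient_id = prof$patient_id,
                                   hospital_death = death))
  expect_equal(unname(vapply(fit$thresholds, `[[`, 0, "j_value")),
               c(1, 1, 1))
  expect_equal(fit$roc$auc, 1)
  expect_equal(fit$prevalence, 5 / 20)
})

test_that("fitted model round trips through the thresholds JSON interface", {
  co <- simulate_cohort(cohort_sim_config(n_patients = 50, seed = 23))
  prof <- aggregate_weekly(co$daily)
  fit <- fifa_fit(prof, co$outcomes)
  path <- withr::local_tempfile(fileext = ".json")
  write_thresholds_json(fit$thresholds, path)
  back <- read_thresholds_json(path)
  expect_equal(fifa_assign(prof, back), fit$scores)
  expect_equal(vapply(back, `[[`, 0, "cutoff"), coef(fit))
})

test_that("model accessors are consistent with the score table", {
  co <- simulate_cohort(cohort_sim_config(n_patients = 45, seed = 29))
  prof <- aggregate_weekly(co$daily)
  fit <- fifa_fit(prof, co$outcomes)
  expect_equal(fitted(fit), fit$scores$total)
  expect_equal(predict(fit), fit$scores)
  expect_equal(predict(fit, prof), fit$scores)
  s <- summary(fit)
  expect_s3_class(s, "summary.fifa")
  expect_equal(s$thresholds$cutoff, unname(coef(fit)))
  expect_equal(s$prevalence, fit$prevalence)
  expect_output(print(fit), "FIFA frailty score fit")
})
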