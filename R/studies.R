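#' Null-calibration study of the FIFA score
#'
#' Simulates pairs of independent null cohorts (latent frailty disconnected
#' from death, \code{frailty_effect = 0}), derives the score's thresholds on
#' the training cohort and evaluates the resulting ordinal score on the test
#' cohort. Under the null the out-of-sample AUC distribution must centre on
#' 0.5; evaluation is out-of-sample because Youden-derived cutoffs are
#' optimistically biased on the cohort that produced them. Replicates whose
#' training cohort has no deaths, or whose test cohort lacks a case or a
#' control, are skipped and counted.
#'
#' @param n_reps Number of replicate cohort pairs.
#' @param n_patients Patients per cohort.
#' @param seed Base seed; each replicate derives its own seeds from it.
#' @return List: \code{auc} (vector over usable replicates),
#'   \code{mean_auc}, \code{se} (standard error of the mean),
#'   \code{n_used}, \code{n_skipped}.
#' @export
study_null_calibration <- function(n_reps = 200L, n_patients = 50L,
                                   seed = 1L) {
  aucs <- numeric(0)
  skipped <- 0L
  for (r in seq_len(n_reps)) {
    tr <- simulate_cohort(cohort_sim_config(n_patients = n_patients,
                                            seed = seed * 1000L + r,
                                            frailty_effect = 0))
    te <- simulate_cohort(cohort_sim_config(n_patients = n_patients,
                                            seed = seed * 1000L + 500L + r,
                                            frailty_effect = 0))
    y_tr <- tr$outcomes$hospital_death
    y_te <- te$outcomes$hospital_death
    if (sum(y_tr) == 0L || sum(y_te) == 0L || sum(!y_te) == 0L) {
      skipped <- skipped + 1L
      next
    }
    fit <- fifa_fit(aggregate_weekly(tr$daily), tr$outcomes)
    sc <- predict(fit, aggregate_weekly(te$daily))
    y <- y_te[match(sc$patient_id, te$outcomes$patient_id)]
    aucs <- c(aucs, auc_rank(sc$total, y, "positive")$auc)
  }
  list(auc = aucs, mean_auc = mean(aucs),
       se = stats::sd(aucs) / sqrt(length(aucs)),
       n_used = length(aucs), n_skipped = skipped)
}

#' Parameter-recovery study with a planted stress effect
#'
#' Simulates large cohorts in which only the overall stress level carries
#' the latent mortality signal (loading +1) alongside a weak negative step
#' loading, fits the score, and asks two questions per replicate: (1) does
#' the profile-derived stress cutoff fall inside the central 90\% of the
#' planted discriminating region — the interval of noiseless patient-level
#' stress means between the survivor and death class centroids (latent
#' table), shrunk 5\% per side; (2) does the fitted FIFA score's AUC exceed
#' the AUC of every single channel that was not planted to carry the signal?
#' The latent-table oracle cutoff (Youden on noiseless means) is also
#' recorded.
#'
#' @param n_reps Number of replicates.
#' @param n_patients Patients per cohort.
#' @param seed Base seed.
#' @param frailty_effect Logistic slope of the planted effect.
#' @return List with \code{replicates} (data frame: derived and oracle
#'   cutoffs, region bounds, \code{in_region}, \code{fifa_auc},
#'   \code{best_misloaded_auc}, \code{fifa_beats_misloaded}),
#'   \code{prop_in_region} and \code{prop_fifa_beats}.
#' @export
study_parameter_recovery <- function(n_reps = 200L, n_patients = 2000L,
                                     seed = 1L, frailty_effect = 2) {
  planted <- "stress_overall"
  misloaded <- setdiff(fifa_parameters(), planted)
  dirs <- fifa_default_directions()
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- cohort_sim_config(
      n_patients = n_patients, seed = seed * 1000L + r,
      frailty_effect = frailty_effect,
      channel_loadings = c(stress_overall = 1, steps = -0.2,
                           distance_km = 0, hr_min = 0, hr_max = 0,
                           stress_high_min = 0, stress_rest_min = 0))
    co <- simulate_cohort(cfg)
    prof <- aggregate_weekly(co$daily)
    fit <- fifa_fit(prof, co$outcomes)
    y_all <- co$outcomes$hospital_death
    lat <- co$latent
    lo <- mean(lat$mean_stress_overall[!y_all])
    hi <- mean(lat$mean_stress_overall[y_all])
    w <- hi - lo
    derived <- coef(fit)[["stress"]]
    oracle <- youden_threshold(lat$mean_stress_overall, y_all,
                               "positive")$cutoff
    y <- y_all[match(prof$patient_id, co$outcomes$patient_id)]
    ch_auc <- vapply(misloaded, function(p) {
      auc_rank(prof[[p]], y, dirs[[p]])$auc
    }, 0)
    rows[[r]] <- data.frame(
      derived_cutoff = derived, oracle_cutoff = oracle,
      region_low = lo + 0.05 * w, region_high = hi - 0.05 * w,
      in_region = derived >= lo + 0.05 * w & derived <= hi - 0.05 * w,
      fifa_auc = fit$roc$auc,
      best_misloaded_auc = max(ch_auc),
      fifa_beats_misloaded = fit$roc$auc > max(ch_auc))
  }
  reps <- do.call(rbind, rows)
  list(replicates = reps,
       prop_in_region = mean(reps$in_region),
       prop_fifa_beats = mean(reps$fifa_beats_misloaded))
}
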