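#' Channel defaults for the cohort simulator
#'
#' Per-parameter baselines (native units), between-patient scales (the units
#' one unit of dimensionless loading corresponds to) and within-patient daily
#' noise standard deviations. Baselines are plausible values for an elderly
#' pre-intervention cohort (for example 4000 steps/day, maximum heart rate
#' 110 bpm, overall daily stress 35/100); analyses downstream must not depend
#' on the specific baselines, only on loadings and effects.
#'
#' @return Data frame with columns \code{parameter}, \code{baseline},
#'   \code{scale}, \code{noise_sd}.
#' @export
fifa_channel_defaults <- function() {
  data.frame(
    parameter = fifa_parameters(),
    baseline = c(4000, 2.5, 55, 110, 35, 60, 600, 60, 240, 45, 345),
    scale    = c(1200, 0.8,  6,  10, 10, 30, 120, 20,  50, 20,  60),
    noise_sd = c(1000, 0.7,  4,   8,  8, 25,  90, 20,  45, 15,  50),
    stringsAsFactors = FALSE
  )
}

#' Default latent-frailty loadings
#'
#' Dimensionless loading of the latent frailty factor on each channel's
#' patient-level mean, in units of the channel scale. Signs follow the
#' observed mortality correlations: stress burden and heart-rate maximum load
#' positively, minutes at rest and walking negatively; sleep channels carry
#' no loading because sleep is not part of the score.
#'
#' @return Named numeric vector over [fifa_parameters()].
#' @export
fifa_default_loadings <- function() {
  c(steps = -0.2, distance_km = -0.2, hr_min = 0.3, hr_max = 0.7,
    stress_overall = 1.0, stress_high_min = 0.9, stress_rest_min = -0.7,
    sleep_deep_min = 0, sleep_light_min = 0, sleep_awake_min = 0,
    sleep_total_min = 0)
}

#' Configuration for the synthetic cohort generator
#'
#' @param n_patients Number of patients (>= 2). Default 50, the size of a
#'   single-centre proof-of-concept cohort.
#' @param days_per_patient Device-days per patient (>= 3). Default 9: one
#'   full week retained after the first/last-day trim.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param frailty_effect Logistic slope linking latent frailty to death.
#' @param baseline_death_logit Intercept of the death model; the default
#'   \code{qlogis(0.06)} matches a 6\% in-hospital mortality at zero frailty.
#' @param channel_loadings Named vector as [fifa_default_loadings()]; entries
#'   override the defaults.
#' @param noise_sd Named vector of within-patient daily standard deviations
#'   (native units); entries override [fifa_channel_defaults()].
#' @param missing_rate Probability, in [0, 1), that any one daily field is a
#'   device gap (missing completely at random).
#' @return An object of class \code{"cohort_sim_config"}.
#' @seealso [simulate_cohort()]
#' @export
cohort_sim_config <- function(n_patients = 50L, days_per_patient = 9L,
                              seed = 1L, frailty_effect = 2,
                              baseline_death_logit = stats::qlogis(0.06),
                              channel_loadings = NULL, noise_sd = NULL,
                              missing_rate = 0.02) {
  if (n_patients < 2L) stop("n_patients must be >= 2", call. = FALSE)
  if (days_per_patient < 3L) stop("days_per_patient must be >= 3", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  }
  loads <- fifa_default_loadings()
  if (!is.null(channel_loadings)) {
    bad <- setdiff(names(channel_loadings), names(loads))
    if (length(bad)) stop("unknown parameter(s) in channel_loadings: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    loads[names(channel_loadings)] <- channel_loadings
  }
  ch <- fifa_channel_defaults()
  sds <- stats::setNames(ch$noise_sd, ch$parameter)
  if (!is.null(noise_sd)) {
    bad <- setdiff(names(noise_sd), names(sds))
    if (length(bad)) stop("unknown parameter(s) in noise_sd: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    sds[names(noise_sd)] <- noise_sd
  }
  if (any(sds < 0)) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients),
                 days_per_patient = as.integer(days_per_patient),
                 seed = as.integer(seed),
                 frailty_effect = frailty_effect,
                 baseline_death_logit = baseline_death_logit,
                 channel_loadings = loads,
                 noise_sd = sds,
                 missing_rate = missing_rate),
            class = "cohort_sim_config")
}

#' Simulate a wearable-monitoring cohort with a latent frailty factor
#'
#' Each patient carries a scalar latent frailty \eqn{f_i \sim N(0,1)}. A
#' channel's patient-level mean is \code{baseline + loading * scale * f_i};
#' daily values add independent Gaussian noise and are clipped to the
#' channel's valid range (stress score to [0, 100], all quantities to >= 0).
#' Heart-rate min/max are drawn jointly and ordered so \code{hr_min <=
#' hr_max} always holds; rest minutes are capped so stress-state minutes fit
#' in a day; total sleep is floored at deep + light sleep. In-hospital death
#' is Bernoulli with logit \code{baseline_death_logit + frailty_effect *
#' f_i}. Device gaps are inserted completely at random at
#' \code{missing_rate}.
#'
#' With \code{frailty_effect = 0} (or all loadings zero) the design is a null
#' scenario: no parameter carries mortality signal.
#'
#' @param config A [cohort_sim_config()].
#' @return List of class \code{"fifa_cohort"} with elements \code{daily}
#'   (device-day records), \code{outcomes} (\code{patient_id},
#'   \code{hospital_death}), \code{latent} (per patient: frailty factor,
#'   true death probability, and the noiseless channel means
#'   \code{mean_<parameter>} — the oracle table for recovery studies) and
#'   \code{config}.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_sim_config(n_patients = 20, seed = 7))
#' head(cohort$daily)
#' table(cohort$outcomes$hospital_death)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(config$seed, kind = "Mersenne-Twister")
  n <- config$n_patients
  d <- config$days_per_patient
  ch <- fifa_channel_defaults()
  params <- ch$parameter
  ids <- sprintf("P%04d", seq_len(n))

  f <- stats::rnorm(n)
  p_death <- stats::plogis(config$baseline_death_logit +
                             config$frailty_effect * f)
  death <- stats::rbinom(n, 1L, p_death) == 1L

  # patient-level true means, one column per channel
  mu <- matrix(rep(ch$baseline, each = n), nrow = n,
               dimnames = list(NULL, params))
  for (p in params) {
    mu[, p] <- mu[, p] + config$channel_loadings[[p]] *
      ch$scale[ch$parameter == p] * f
  }

  nd <- n * d
  pid <- rep(ids, each = d)
  vals <- matrix(NA_real_, nrow = nd, ncol = length(params),
                 dimnames = list(NULL, params))
  for (p in params) {
    vals[, p] <- rep(mu[, p], each = d) +
      stats::rnorm(nd, sd = config$noise_sd[[p]])
  }
  # range constraints (clipping after noise slightly attenuates extremes)
  vals <- pmax(vals, 0)
  vals[, "stress_overall"] <- pmin(vals[, "stress_overall"], 100)
  hr <- cbind(vals[, "hr_min"], vals[, "hr_max"])
  vals[, "hr_min"] <- pmin(hr[, 1], hr[, 2])
  vals[, "hr_max"] <- pmax(hr[, 1], hr[, 2])
  vals[, "stress_rest_min"] <- pmin(vals[, "stress_rest_min"],
                                    1440 - vals[, "stress_high_min"])
  vals[, "sleep_total_min"] <- pmax(vals[, "sleep_total_min"],
                                    vals[, "sleep_deep_min"] +
                                      vals[, "sleep_light_min"])
  vals[, "steps"] <- round(vals[, "steps"])

  if (config$missing_rate > 0) {
    gaps <- matrix(stats::runif(length(vals)) < config$missing_rate,
                   nrow = nd)
    vals[gaps] <- NA_real_
  }

  daily <- data.frame(patient_id = pid,
                      day_index = rep(seq_len(d) - 1L, times = n),
                      stringsAsFactors = FALSE)
  daily[params] <- as.data.frame(vals)

  latent <- data.frame(patient_id = ids, frailty = f, death_prob = p_death,
                       stringsAsFactors = FALSE)
  latent[paste0("mean_", params)] <- as.data.frame(mu)

  structure(list(
    daily = validate_daily(daily),
    outcomes = data.frame(patient_id = ids, hospital_death = death,
                          stringsAsFactors = FALSE),
    latent = latent,
    config = config
  ), class = "fifa_cohort")
}

#' @export
print.cohort_sim_config <- function(x, ...) {
  cat("Cohort simulation config:", x$n_patients, "patients x",
      x$days_per_patient, "days, seed", x$seed, "\n")
  cat("  frailty effect:", x$frailty_effect,
      " baseline death logit:", round(x$baseline_death_logit, 3),
      " missing rate:", x$missing_rate, "\n")
  nz <- x$channel_loadings[x$channel_loadings != 0]
  cat("  non-zero loadings:",
      if (length(nz)) paste(names(nz), nz, sep = "=", collapse = ", ")
      else "(none — null scenario)", "\n")
  invisible(x)
}

#' @export
print.fifa_cohort <- function(x, ...) {
  cat("Simulated cohort:", nrow(x$outcomes), "patients,",
      nrow(x$daily), "device-days,",
      sum(x$outcomes$hospital_death), "death(s)\n")
  invisible(x)
}
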