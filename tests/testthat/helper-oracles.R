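# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's own code paths.

# AUC by exhaustive enumeration of all case-control pairs, ties counted 1/2
brute_auc <- function(values, outcomes, direction = "positive") {
  x <- if (direction == "negative") -values else values
  cases <- x[as.logical(outcomes)]
  controls <- x[!as.logical(outcomes)]
  tot <- 0
  for (cs in cases) {
    for (ct in controls) {
      tot <- tot + (cs > ct) + 0.5 * (cs == ct)
    }
  }
  tot / (length(cases) * length(controls))
}

# Youden scan by direct evaluation of sens/spec at every candidate cutoff;
# ties compared on exact integer counts so equal-J cutoffs are true ties
brute_youden <- function(values, outcomes, direction = "positive") {
  y <- as.logical(outcomes)
  n1 <- sum(y)
  n0 <- sum(!y)
  v <- sort(unique(values))
  cand <- c(-Inf, if (length(v) > 1) (v[-length(v)] + v[-1]) / 2, Inf)
  best <- NULL
  for (c0 in cand) {
    called <- if (direction == "positive") values > c0 else values < c0
    sens_cnt <- sum(called[y])
    spec_cnt <- sum(!called[!y])
    j_scaled <- sens_cnt * n0 + spec_cnt * n1 - n1 * n0
    if (is.null(best) || j_scaled > best$j_scaled ||
        (j_scaled == best$j_scaled &&
           (sens_cnt > best$sens_cnt ||
              (sens_cnt == best$sens_cnt && c0 < best$cutoff)))) {
      best <- list(cutoff = c0, j_scaled = j_scaled, sens_cnt = sens_cnt,
                   j = sens_cnt / n1 + spec_cnt / n0 - 1,
                   sens = sens_cnt / n1, spec = spec_cnt / n0)
    }
  }
  best
}

# Independent trim-then-average re-implementation of the weekly rule
brute_weekly_mean <- function(day_values) {
  retained <- day_values[-c(1, length(day_values))]
  if (all(is.na(retained))) return(NA_real_)
  mean(retained, na.rm = TRUE)
}

# The observed cohort reconstructed from published group sizes and deaths:
# 11/10/21/8 patients at FIFA totals 0-3, with 0/0/1/2 in-hospital deaths
observed_cohort <- function() {
  totals <- rep(0:3, c(11L, 10L, 21L, 8L))
  deaths <- unlist(mapply(function(n, d) c(rep(FALSE, n - d), rep(TRUE, d)),
                          c(11L, 10L, 21L, 8L), c(0L, 0L, 1L, 2L),
                          SIMPLIFY = FALSE))
  data.frame(patient_id = sprintf("T%02d", seq_along(totals)),
             total = totals, hospital_death = deaths,
             stringsAsFactors = FALSE)
}

# A tiny valid daily table for IO tests
tiny_daily <- function() {
  d <- expand.grid(day_index = 0:4, patient_id = c("A", "B"),
                   stringsAsFactors = FALSE)[, 2:1]
  n <- nrow(d)
  set.seed(99)
  d$steps <- round(runif(n, 1000, 8000))
  d$distance_km <- round(runif(n, 0.5, 6), 2)
  d$hr_min <- round(runif(n, 45, 60))
  d$hr_max <- d$hr_min + round(runif(n, 20, 70))
  d$stress_overall <- round(runif(n, 10, 90))
  d$stress_high_min <- round(runif(n, 0, 200))
  d$stress_rest_min <- round(runif(n, 200, 900))
  d$sleep_deep_min <- round(runif(n, 30, 90))
  d$sleep_light_min <- round(runif(n, 120, 300))
  d$sleep_awake_min <- round(runif(n, 0, 60))
  d$sleep_total_min <- d$sleep_deep_min + d$sleep_light_min +
    round(runif(n, 0, 40))
  d
}
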