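#' Scoreable tracker parameters
#'
#' The closed set of daily wearable summary parameters the pipeline knows how
#' to aggregate and screen. Each name is both a column of the daily CSV and a
#' column of the weekly profile table. Extra columns in input files (for
#' example calories or floors climbed) are carried through untouched but are
#' never scored.
#'
#' @return Character vector of parameter names.
#' @export
#' @examples
#' fifa_parameters()
fifa_parameters <- function() {
  c("steps", "distance_km", "hr_min", "hr_max",
    "stress_overall", "stress_high_min", "stress_rest_min",
    "sleep_deep_min", "sleep_light_min", "sleep_awake_min", "sleep_total_min")
}

#' Default risk directions for each tracker parameter
#'
#' Whether larger weekly values of a parameter indicate higher in-hospital
#' mortality risk (\code{"positive"}) or lower risk (\code{"negative"}).
#' Heart-rate extremes and stress burden load positively; step count, walking
#' distance, minutes at rest and total/deep sleep load negatively.
#'
#' @return Named character vector over [fifa_parameters()], values
#'   \code{"positive"} or \code{"negative"}.
#' @export
fifa_default_directions <- function() {
  c(steps = "negative", distance_km = "negative",
    hr_min = "positive", hr_max = "positive",
    stress_overall = "positive", stress_high_min = "positive",
    stress_rest_min = "negative",
    sleep_deep_min = "negative", sleep_light_min = "positive",
    sleep_awake_min = "positive", sleep_total_min = "negative")
}

# internal: validate a direction string
check_direction <- function(direction) {
  if (!is.character(direction) || length(direction) != 1L ||
      !direction %in% c("positive", "negative")) {
    stop("`direction` must be \"positive\" or \"negative\"", call. = FALSE)
  }
  direction
}
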