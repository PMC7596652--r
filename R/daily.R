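#' Validate a table of daily wearable records
#'
#' Checks the row-level invariants of device-day records: all quantities
#' non-negative, daily stress score within [0, 100], \code{hr_min <= hr_max}
#' when both are present, deep + light sleep not exceeding total sleep, and
#' high-stress plus rest minutes fitting in a day (1440 min). Missing values
#' (device gaps) are allowed in every non-identifier field.
#'
#' @param daily Data frame with columns \code{patient_id}, \code{day_index}
#'   and the parameters of [fifa_parameters()] (extra columns allowed).
#' @return The input, invisibly, sorted by \code{(patient_id, day_index)}.
#' @export
validate_daily <- function(daily) {
  stopifnot(is.data.frame(daily))
  required <- c("patient_id", "day_index", fifa_parameters())
  missing_cols <- setdiff(required, names(daily))
  if (length(missing_cols)) {
    stop("daily table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyNA(daily$patient_id) || anyNA(daily$day_index)) {
    stop("patient_id and day_index must not be missing", call. = FALSE)
  }
  if (any(daily$day_index < 0 | daily$day_index != floor(daily$day_index))) {
    stop("day_index must be a non-negative integer ordinal", call. = FALSE)
  }
  fail <- function(rows, rule) {
    if (any(rows, na.rm = TRUE)) {
      stop(sprintf("daily record invariant violated (%s) at row(s) %s",
                   rule, paste(utils::head(which(rows), 5L), collapse = ", ")),
           call. = FALSE)
    }
  }
  for (p in fifa_parameters()) {
    fail(!is.na(daily[[p]]) & daily[[p]] < 0, paste0(p, " >= 0"))
  }
  so <- daily$stress_overall
  fail(!is.na(so) & (so < 0 | so > 100), "stress_overall in [0,100]")
  fail(!is.na(daily$hr_min) & !is.na(daily$hr_max) &
         daily$hr_min > daily$hr_max, "hr_min <= hr_max")
  s3 <- !is.na(daily$sleep_deep_min) & !is.na(daily$sleep_light_min) &
    !is.na(daily$sleep_total_min)
  fail(s3 & daily$sleep_deep_min + daily$sleep_light_min >
         daily$sleep_total_min + 1e-9,
       "sleep_deep_min + sleep_light_min <= sleep_total_min")
  sb <- !is.na(daily$stress_high_min) & !is.na(daily$stress_rest_min)
  fail(sb & daily$stress_high_min + daily$stress_rest_min > 1440 + 1e-9,
       "stress_high_min + stress_rest_min <= 1440")
  dup <- duplicated(daily[c("patient_id", "day_index")])
  if (any(dup)) {
    stop("duplicate (patient_id, day_index) at row(s) ",
         paste(utils::head(which(dup), 5L), collapse = ", "), call. = FALSE)
  }
  ord <- order(daily$patient_id, daily$day_index)
  invisible(daily[ord, , drop = FALSE])
}

#' Read daily wearable records from CSV
#'
#' Expects the header
#' \code{patient_id,day_index,steps,distance_km,hr_min,hr_max,stress_overall,
#' stress_high_min,stress_rest_min,sleep_deep_min,sleep_light_min,
#' sleep_awake_min,sleep_total_min}. Empty cells are read as \code{NA}
#' (device gaps). Extra columns are retained but not scored. Rows are
#' validated against the daily-record invariants and returned sorted by
#' \code{(patient_id, day_index)}.
#'
#' @param path Path to a UTF-8 CSV file with \code{.} decimal separator.
#' @return Data frame of daily records.
#' @seealso [write_daily_csv()], [aggregate_weekly()]
#' @export
read_daily_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  daily <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(patient_id = "character"))
  out <- validate_daily(daily)
  rownames(out) <- NULL
  out
}

#' Write daily wearable records to CSV
#'
#' Inverse of [read_daily_csv()]: \code{NA} is written as an empty cell so a
#' write/read round trip reproduces the record table exactly.
#'
#' @param daily Data frame of daily records (validated before writing).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_daily_csv <- function(daily, path) {
  daily <- validate_daily(daily)
  utils::write.csv(daily, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an outcome table from CSV
#'
#' Expects columns \code{patient_id,hospital_death} with the death indicator
#' coded 0/1. Patient ids must be unique.
#'
#' @param path Path to the outcome CSV.
#' @return Data frame with \code{patient_id} (character) and
#'   \code{hospital_death} (logical).
#' @export
read_outcome_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(patient_id = "character"))
  validate_outcomes(out)
}

#' @rdname read_outcome_csv
#' @param outcomes Data frame with \code{patient_id} and
#'   \code{hospital_death} (0/1 or logical).
#' @export
validate_outcomes <- function(outcomes) {
  stopifnot(is.data.frame(outcomes))
  missing_cols <- setdiff(c("patient_id", "hospital_death"), names(outcomes))
  if (length(missing_cols)) {
    stop("outcome table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(outcomes$patient_id)) {
    stop("patient_id must be unique in the outcome table", call. = FALSE)
  }
  hd <- outcomes$hospital_death
  if (anyNA(hd) || !all(hd %in% c(0, 1))) {
    stop("hospital_death must be 0/1 with no missing values", call. = FALSE)
  }
  outcomes$patient_id <- as.character(outcomes$patient_id)
  outcomes$hospital_death <- as.logical(hd)
  outcomes
}

#' @rdname read_outcome_csv
#' @export
write_outcome_csv <- function(outcomes, path) {
  outcomes <- validate_outcomes(outcomes)
  outcomes$hospital_death <- as.integer(outcomes$hospital_death)
  utils::write.csv(outcomes, path, row.names = FALSE)
  invisible(path)
}
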