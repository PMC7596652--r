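#' Aggregate daily records into weekly patient profiles
#'
#' Implements the monitoring-window averaging rule: for each patient the
#' first and the last recorded day are dropped (they are incomplete device
#' days by construction of a wear period), and every tracker parameter is
#' averaged over the remaining days, ignoring missing values. Patients
#' retaining fewer than \code{min_days} days are excluded from the output and
#' reported via a warning and the \code{"excluded"} attribute.
#'
#' @param daily Data frame of daily records (see [read_daily_csv()]).
#' @param min_days Minimum number of retained days a patient needs to get a
#'   profile. Default 3: keeps short compliance usable while ruling out
#'   single-day profiles.
#' @return Data frame with columns \code{patient_id}, \code{n_days_used} and
#'   one mean per parameter; attribute \code{"excluded"} holds the ids of
#'   dropped patients. Empty input gives an empty profile table.
#' @export
#' @examples
#' d <- simulate_cohort(cohort_sim_config(n_patients = 4, seed = 1))
#' aggregate_weekly(d$daily)
aggregate_weekly <- function(daily, min_days = 3L) {
  stopifnot(min_days >= 1L)
  params <- fifa_parameters()
  empty <- data.frame(patient_id = character(), n_days_used = integer())
  for (p in params) empty[[p]] <- numeric()
  if (nrow(daily) == 0L) {
    attr(empty, "excluded") <- character()
    return(empty)
  }
  daily <- validate_daily(daily)

  # trim first/last day per patient by ordinal position (rows are sorted)
  id <- as.character(daily$patient_id)
  first <- !duplicated(id)
  last <- !duplicated(id, fromLast = TRUE)
  keep <- !(first | last)
  kept <- daily[keep, , drop = FALSE]
  kid <- factor(id[keep], levels = unique(id))

  n_days <- integer(length(levels(kid)))
  names(n_days) <- levels(kid)
  if (nrow(kept)) {
    tb <- table(kid)
    n_days[names(tb)] <- as.integer(tb)
  }

  prof <- data.frame(patient_id = levels(kid),
                     n_days_used = as.integer(n_days),
                     stringsAsFactors = FALSE)
  if (nrow(kept)) {
    m <- as.matrix(kept[params])
    present <- !is.na(m)
    m[!present] <- 0
    sums <- rowsum(m, kid)                    # level order
    cnts <- rowsum(present + 0, kid)
    means <- sums / cnts                      # NaN where no non-null day
    means[cnts == 0] <- NA_real_
    prof[params] <- means[prof$patient_id, , drop = FALSE]
  } else {
    prof[params] <- NA_real_
  }

  drop_ids <- prof$patient_id[prof$n_days_used < min_days]
  prof <- prof[prof$n_days_used >= min_days, , drop = FALSE]
  rownames(prof) <- NULL
  if (length(drop_ids)) {
    warning(length(drop_ids), " patient(s) excluded with fewer than ",
            min_days, " retained monitoring days: ",
            paste(utils::head(drop_ids, 10L), collapse = ", "),
            call. = FALSE)
  }
  if (nrow(prof) == 0L && length(drop_ids)) {
    warning("all patients were excluded by the min_days rule", call. = FALSE)
  }
  attr(prof, "excluded") <- drop_ids
  prof
}

#' Read or write weekly profile tables
#'
#' Weekly CSV schema: \code{patient_id,n_days_used,<one column per
#' parameter>}; empty cell = missing.
#'
#' @param path CSV path.
#' @return For the reader, a data frame of weekly profiles.
#' @export
read_weekly_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  prof <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(patient_id = "character"))
  required <- c("patient_id", "n_days_used", fifa_parameters())
  missing_cols <- setdiff(required, names(prof))
  if (length(missing_cols)) {
    stop("weekly table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  prof
}

#' @rdname read_weekly_csv
#' @param profiles Data frame of weekly profiles.
#' @export
write_weekly_csv <- function(profiles, path) {
  utils::write.csv(profiles, path, row.names = FALSE, na = "")
  invisible(path)
}
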