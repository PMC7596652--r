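#' Edmonton Frail Scale classification
#'
#' Bands the 0-17 point EFS total into its five categories: 0-5 not frail,
#' 6-7 vulnerable, 8-9 mild, 10-11 moderate, >=12 severe frailty. The binary
#' frailty definition used for prevalence counts mild, moderate and severe
#' as frail. The ordinal code (not_frail=0 ... severe=4) orders categories
#' by increasing frailty so ROC analyses can use a uniform positive
#' direction.
#'
#' @param efs_points Integer vector of EFS totals, each in 0-17.
#' @param patient_id Optional ids carried into the result.
#' @return Data frame: \code{patient_id} (if given), \code{efs_points},
#'   \code{category} (factor), \code{ordinal} (0-4), \code{frail_binary}.
#' @export
#' @examples
#' efs_classify(c(3, 7, 9, 11, 14))
efs_classify <- function(efs_points, patient_id = NULL) {
  if (anyNA(efs_points) || any(efs_points < 0 | efs_points > 17 |
                                 efs_points != floor(efs_points))) {
    stop("efs_points must be integers in 0-17", call. = FALSE)
  }
  levs <- c("not_frail", "vulnerable", "mild", "moderate", "severe")
  ordinal <- findInterval(efs_points, c(0, 6, 8, 10, 12)) - 1L
  out <- data.frame(efs_points = as.integer(efs_points),
                    category = factor(levs[ordinal + 1L], levels = levs),
                    ordinal = ordinal,
                    frail_binary = ordinal >= 2L)
  if (!is.null(patient_id)) {
    out <- cbind(data.frame(patient_id = as.character(patient_id),
                            stringsAsFactors = FALSE), out)
  }
  out
}

#' 6-minute-walk-test gait-speed classification
#'
#' Converts the distance walked in 6 minutes (360 s) to a gait speed and
#' bands it: very slow < 0.5 m/s, slow 0.5-0.83 m/s (inclusive), normal
#' > 0.83 m/s; an infeasible test (general weakness, bedridden,
#' wheelchair-bound, pain) is its own most-frail category. The binary
#' frailty definition is "anything but a normal walker". Ordinal code:
#' normal=0, slow=1, very_slow=2, not_feasible=3.
#'
#' @param feasible Logical vector: was the walk test performed?
#' @param distance_m Distance in metres for feasible tests; \code{NA}
#'   where infeasible.
#' @param patient_id Optional ids carried into the result.
#' @return Data frame: \code{patient_id} (if given), \code{feasible},
#'   \code{distance_m}, \code{speed_mps}, \code{category} (factor),
#'   \code{ordinal}, \code{frail_binary}.
#' @export
#' @examples
#' gait_classify(c(TRUE, TRUE, TRUE, FALSE), c(360, 180, 120, NA))
gait_classify <- function(feasible, distance_m, patient_id = NULL) {
  feasible <- as.logical(feasible)
  if (anyNA(feasible)) stop("feasible must be TRUE/FALSE", call. = FALSE)
  if (length(distance_m) != length(feasible)) {
    stop("feasible and distance_m must have equal length", call. = FALSE)
  }
  if (any(feasible & is.na(distance_m))) {
    stop("feasible test(s) with missing distance_m", call. = FALSE)
  }
  if (any(feasible & distance_m < 0, na.rm = TRUE)) {
    stop("distance_m must be >= 0", call. = FALSE)
  }
  speed <- ifelse(feasible, distance_m / 360, NA_real_)
  levs <- c("normal", "slow", "very_slow", "not_feasible")
  ordinal <- ifelse(!feasible, 3L,
                    ifelse(speed < 0.5, 2L, ifelse(speed <= 0.83, 1L, 0L)))
  out <- data.frame(feasible = feasible,
                    distance_m = ifelse(feasible, distance_m, NA_real_),
                    speed_mps = speed,
                    category = factor(levs[ordinal + 1L], levels = levs),
                    ordinal = as.integer(ordinal),
                    frail_binary = ordinal >= 1L)
  if (!is.null(patient_id)) {
    out <- cbind(data.frame(patient_id = as.character(patient_id),
                            stringsAsFactors = FALSE), out)
  }
  out
}

#' Read the comparator assessments CSV
#'
#' Schema: \code{patient_id,efs_points,gait_feasible,gait_distance_m}.
#'
#' @param path CSV path.
#' @return List with elements \code{efs} and \code{gait}, each a classified
#'   data frame.
#' @export
read_comparators_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(patient_id = "character"))
  required <- c("patient_id", "efs_points", "gait_feasible",
                "gait_distance_m")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("comparators table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  list(efs = efs_classify(raw$efs_points, raw$patient_id),
       gait = gait_classify(as.logical(raw$gait_feasible),
                            raw$gait_distance_m, raw$patient_id))
}
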