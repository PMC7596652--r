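#' Screen every tracker parameter for mortality discrimination
#'
#' Runs a rank-based ROC analysis ([auc_rank()]) of each weekly-profile
#' parameter against the in-hospital mortality outcome, using each
#' parameter's default risk direction (overridable), and returns the rows
#' ordered by descending AUC — the single-parameter screen from which the
#' score's categories were chosen.
#'
#' @param profiles Weekly profile table.
#' @param outcomes Outcome table (\code{patient_id}, \code{hospital_death}).
#' @param directions Named direction vector; defaults to
#'   [fifa_default_directions()].
#' @param conf_level Confidence level for the AUC intervals.
#' @return Data frame with one row per parameter: \code{parameter},
#'   \code{direction}, \code{auc}, \code{ci_low}, \code{ci_high},
#'   \code{n_cases}, \code{n_controls}, ordered by descending AUC.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_sim_config(n_patients = 80, seed = 3))
#' prof <- aggregate_weekly(cohort$daily)
#' parameter_screen(prof, cohort$outcomes)
parameter_screen <- function(profiles, outcomes,
                             directions = fifa_default_directions(),
                             conf_level = 0.95) {
  outcomes <- validate_outcomes(outcomes)
  dat <- merge(profiles, outcomes, by = "patient_id")
  params <- intersect(fifa_parameters(), names(dat))
  rows <- lapply(params, function(p) {
    dir <- if (p %in% names(directions)) directions[[p]] else "positive"
    roc <- auc_rank(dat[[p]], dat$hospital_death, dir, conf_level)
    data.frame(parameter = p, direction = dir, auc = roc$auc,
               ci_low = roc$ci_low, ci_high = roc$ci_high,
               n_cases = roc$n_cases, n_controls = roc$n_controls,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$auc), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Head-to-head comparison of frailty instruments
#'
#' Compares the FIFA score against the Edmonton Frail Scale classification
#' and the 6MWT gait-speed category as predictors of hospital mortality.
#' Each instrument enters the ROC analysis as its ordinal stage code with a
#' uniform positive direction (higher stage = more frail); each row also
#' reports the instrument's binary frailty prevalence. Tables are joined on
#' \code{patient_id} (inner join; mismatches reported).
#'
#' @param fifa_scores Score table from [fifa_assign()] / [predict.fifa()].
#' @param efs [efs_classify()] output with \code{patient_id}.
#' @param gait [gait_classify()] output with \code{patient_id}.
#' @param outcomes Outcome table.
#' @param conf_level Confidence level for AUC intervals.
#' @return Object of class \code{"frailty_comparison"}: a data frame with
#'   one row per instrument (\code{score}, \code{auc}, \code{ci_low},
#'   \code{ci_high}, \code{prevalence}, \code{n_cases},
#'   \code{n_controls}), most discriminative first.
#' @export
compare_scores <- function(fifa_scores, efs, gait, outcomes,
                           conf_level = 0.95) {
  outcomes <- validate_outcomes(outcomes)
  tables <- list(
    fifa = data.frame(patient_id = fifa_scores$patient_id,
                      ordinal = fifa_scores$total,
                      frail = fifa_scores$frail_binary),
    efs_c = data.frame(patient_id = efs$patient_id,
                       ordinal = efs$ordinal, frail = efs$frail_binary),
    gsc_6mwt = data.frame(patient_id = gait$patient_id,
                          ordinal = gait$ordinal, frail = gait$frail_binary))
  ids <- Reduce(intersect, c(lapply(tables, `[[`, "patient_id"),
                             list(outcomes$patient_id)))
  if (length(ids) == 0L) {
    stop("no patients shared by all score tables and outcomes",
         call. = FALSE)
  }
  n_all <- length(unique(unlist(lapply(tables, `[[`, "patient_id"))))
  if (length(ids) < n_all) {
    warning(n_all - length(ids),
            " patient(s) not present in every table were dropped",
            call. = FALSE)
  }
  y <- outcomes$hospital_death[match(ids, outcomes$patient_id)]
  rows <- lapply(names(tables), function(nm) {
    tb <- tables[[nm]]
    v <- tb$ordinal[match(ids, tb$patient_id)]
    roc <- auc_rank(v, y, "positive", conf_level)
    data.frame(score = nm, auc = roc$auc, ci_low = roc$ci_low,
               ci_high = roc$ci_high,
               prevalence = mean(tb$frail[match(ids, tb$patient_id)]),
               n_cases = roc$n_cases, n_controls = roc$n_controls,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$auc), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("frailty_comparison", "data.frame")
  out
}

#' @export
print.frailty_comparison <- function(x, digits = 3, ...) {
  cat("Frailty instruments vs hospital mortality",
      sprintf("(%d case(s), %d control(s))\n",
              x$n_cases[1], x$n_controls[1]))
  df <- data.frame(score = x$score,
                   AUC = round(x$auc, digits),
                   CI = sprintf("%.*f-%.*f", digits, x$ci_low,
                                digits, x$ci_high),
                   prevalence = sprintf("%.1f%%", 100 * x$prevalence))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Render an ROC screen or comparison as aligned text
#'
#' @param screen Output of [parameter_screen()] and/or [compare_scores()],
#'   given as a named list of data frames; each becomes a section.
#' @return Character vector of report lines, invisibly printed.
#' @export
render_roc_report <- function(screen) {
  stopifnot(is.list(screen), !is.null(names(screen)))
  lines <- character()
  for (nm in names(screen)) {
    tab <- screen[[nm]]
    lines <- c(lines, nm, strrep("-", nchar(nm)))
    label <- if ("parameter" %in% names(tab)) tab$parameter else tab$score
    lines <- c(lines, sprintf("%-18s AUC %.3f  CI %.3f-%.3f", label,
                              tab$auc, tab$ci_low, tab$ci_high), "")
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
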