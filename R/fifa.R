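#' Default category-to-parameter map of the FIFA score
#'
#' The score draws one point from each of three predefined categories:
#' walking, heart rate and preprocedural stress. By default walking is
#' represented by the daily step count (risk direction negative), heart rate
#' by the daily maximum (positive) and stress by the overall daily stress
#' level (positive). The map is configurable because the operative walking
#' parameter is under-determined at the single-cohort scale.
#'
#' @return Named list with entries \code{walking}, \code{heart_rate},
#'   \code{stress}; each a list of \code{parameter} and \code{direction}.
#' @export
fifa_default_categories <- function() {
  list(walking    = list(parameter = "steps", direction = "negative"),
       heart_rate = list(parameter = "hr_max", direction = "positive"),
       stress     = list(parameter = "stress_overall", direction = "positive"))
}

fifa_stages <- c("no_frailty", "mild_frailty", "moderate_frailty",
                 "severe_frailty")

check_categories <- function(categories) {
  if (!is.list(categories) || length(categories) != 3L ||
      is.null(names(categories)) || anyDuplicated(names(categories))) {
    stop("`categories` must be a named list of exactly 3 categories",
         call. = FALSE)
  }
  pars <- vapply(categories, function(ct) ct$parameter, "")
  if (anyDuplicated(pars)) {
    stop("each category must map to a distinct parameter", call. = FALSE)
  }
  bad <- setdiff(pars, fifa_parameters())
  if (length(bad)) {
    stop("unknown parameter(s) in category map: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  for (ct in categories) check_direction(ct$direction)
  categories
}

#' Fit the FIFA frailty score to a monitored cohort
#'
#' Derives, for each of the three score categories, the weekly-profile cutoff
#' maximising the Youden index against the in-hospital mortality outcome
#' ([youden_threshold()]), then scores every patient: one point per category
#' whose weekly mean breaches its cutoff in the risk direction (strictly
#' above for positive-direction categories, strictly below for negative).
#' The total of 0-3 points maps to four stages — 0 no frailty, 1 mild,
#' 2 moderate, 3 severe — and the binary frailty flag is
#' moderate-or-severe.
#'
#' @param profiles Weekly profile table from [aggregate_weekly()].
#' @param outcomes Outcome table (\code{patient_id}, \code{hospital_death});
#'   joined to the profiles on \code{patient_id}.
#' @param categories Category map as [fifa_default_categories()].
#' @param conf_level Confidence level for the score's ROC interval.
#' @return Object of class \code{"fifa"} with components \code{thresholds}
#'   (one [youden_threshold()] spec per category), \code{categories},
#'   \code{scores} (per-patient points, total, stage, frailty flag on the
#'   training cohort), \code{roc} (rank AUC of the ordinal total against
#'   mortality), \code{prevalence}, \code{n}.
#' @seealso [predict.fifa()], [fifa_assign()], [compare_scores()]
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_sim_config(n_patients = 60, seed = 42))
#' prof <- aggregate_weekly(cohort$daily)
#' fit <- fifa_fit(prof, cohort$outcomes)
#' fit
#' coef(fit)
fifa_fit <- function(profiles, outcomes, categories = fifa_default_categories(),
                     conf_level = 0.95) {
  categories <- check_categories(categories)
  outcomes <- validate_outcomes(outcomes)
  dat <- merge(profiles, outcomes, by = "patient_id")
  if (nrow(dat) < nrow(profiles) || nrow(dat) < nrow(outcomes)) {
    warning(nrow(profiles) - nrow(dat), " profile(s) and ",
            nrow(outcomes) - nrow(dat),
            " outcome(s) had no match and were dropped", call. = FALSE)
  }
  pars <- vapply(categories, function(ct) ct$parameter, "")
  complete <- stats::complete.cases(dat[pars])
  if (!all(complete)) {
    warning(sum(!complete), " patient(s) dropped from threshold derivation ",
            "for missing category parameters", call. = FALSE)
    dat <- dat[complete, , drop = FALSE]
  }
  y <- dat$hospital_death
  thresholds <- lapply(names(categories), function(nm) {
    ct <- categories[[nm]]
    youden_threshold(dat[[ct$parameter]], y, ct$direction,
                     parameter = ct$parameter)
  })
  names(thresholds) <- names(categories)

  fit <- structure(list(thresholds = thresholds, categories = categories,
                        conf_level = conf_level, call = match.call()),
                   class = "fifa")
  fit$scores <- fifa_assign(dat, fit)
  fit$roc <- auc_rank(fit$scores$total, y, "positive", conf_level)
  fit$prevalence <- fifa_prevalence(fit$scores)
  fit$n <- nrow(dat)
  fit
}

#' Assign FIFA points and stages from fixed thresholds
#'
#' Applies an already-derived (or user-supplied) set of category thresholds
#' to weekly profiles. A category scores 1 when the weekly mean strictly
#' exceeds the cutoff (positive direction) or strictly subceeds it
#' (negative direction); a value exactly at the cutoff scores 0.
#'
#' @param profiles Weekly profile table.
#' @param fit A \code{"fifa"} object, or a bare list of
#'   [youden_threshold()] specs named by category.
#' @return Data frame: \code{patient_id}, one \code{point_<category>} column
#'   per category, \code{total} (0-3), \code{stage} (factor: no/mild/
#'   moderate/severe frailty) and \code{frail_binary}
#'   (moderate-or-severe).
#' @export
fifa_assign <- function(profiles, fit) {
  thresholds <- if (inherits(fit, "fifa")) fit$thresholds else fit
  stopifnot(is.list(thresholds), length(thresholds) == 3L)
  res <- data.frame(patient_id = as.character(profiles$patient_id),
                    stringsAsFactors = FALSE)
  for (nm in names(thresholds)) {
    th <- thresholds[[nm]]
    vals <- profiles[[th$parameter]]
    if (is.null(vals)) {
      stop("profiles lack column for configured parameter ", th$parameter,
           call. = FALSE)
    }
    if (anyNA(vals)) {
      stop("missing ", th$parameter, " value for patient(s) ",
           paste(utils::head(res$patient_id[is.na(vals)], 5L),
                 collapse = ", "), call. = FALSE)
    }
    res[[paste0("point_", nm)]] <-
      if (th$direction == "positive") as.integer(vals > th$cutoff)
      else as.integer(vals < th$cutoff)
  }
  res$total <- rowSums(res[paste0("point_", names(thresholds))])
  res$stage <- factor(fifa_stages[res$total + 1L], levels = fifa_stages)
  res$frail_binary <- res$total >= 2L
  res
}

#' Frailty prevalence under the FIFA binary definition
#'
#' Fraction of patients classed moderate or severe frailty.
#'
#' @param scores Score table from [fifa_assign()] / [predict.fifa()].
#' @return A single fraction in [0, 1].
#' @export
fifa_prevalence <- function(scores) {
  if (NROW(scores) == 0L) stop("prevalence undefined on an empty cohort",
                               call. = FALSE)
  mean(scores$frail_binary)
}

#' @export
print.fifa <- function(x, digits = 3, ...) {
  cat("FIFA frailty score fit (", x$n, " patients)\n", sep = "")
  cat("Category thresholds (Youden-derived):\n")
  for (nm in names(x$thresholds)) {
    th <- x$thresholds[[nm]]
    rule <- if (th$direction == "positive") ">" else "<"
    cat(sprintf("  %-11s %-15s 1 point when %s %.4g  (J=%.*f)\n",
                nm, th$parameter, rule, th$cutoff, digits, th$j_value))
  }
  cat(sprintf("Stage counts: %s\n",
              paste(levels(x$scores$stage),
                    tabulate(x$scores$stage, 4L), sep = "=",
                    collapse = ", ")))
  cat(sprintf("Frailty prevalence (moderate+severe): %.1f%%\n",
              100 * x$prevalence))
  cat(sprintf("Mortality discrimination: AUC %.*f (%d%% CI %.*f-%.*f)\n",
              digits, x$roc$auc, round(100 * x$conf_level),
              digits, x$roc$ci_low, digits, x$roc$ci_high))
  invisible(x)
}

#' @export
summary.fifa <- function(object, ...) {
  th <- object$thresholds
  tab <- data.frame(
    category = names(th),
    parameter = vapply(th, function(t) t$parameter, ""),
    direction = vapply(th, function(t) t$direction, ""),
    cutoff = vapply(th, function(t) t$cutoff, 0),
    j_value = vapply(th, function(t) t$j_value, 0),
    sensitivity = vapply(th, function(t) t$sensitivity, 0),
    specificity = vapply(th, function(t) t$specificity, 0),
    row.names = NULL, stringsAsFactors = FALSE)
  out <- list(thresholds = tab,
              stage_counts = table(object$scores$stage),
              prevalence = object$prevalence,
              auc = object$roc$auc,
              ci = c(object$roc$ci_low, object$roc$ci_high),
              n = object$n)
  class(out) <- "summary.fifa"
  out
}

#' @export
print.summary.fifa <- function(x, digits = 3, ...) {
  cat("FIFA score summary —", x$n, "patients\n\n")
  print(x$thresholds, digits = digits, row.names = FALSE)
  cat("\nStages:\n")
  print(x$stage_counts)
  cat(sprintf("\nPrevalence %.1f%%; AUC vs hospital mortality %.*f (CI %.*f-%.*f)\n",
              100 * x$prevalence, digits, x$auc,
              digits, x$ci[1], digits, x$ci[2]))
  invisible(x)
}

#' @export
coef.fifa <- function(object, ...) {
  vapply(object$thresholds, function(t) t$cutoff, 0)
}

#' Score new patients with a fitted FIFA model
#'
#' @param object A \code{"fifa"} fit.
#' @param newdata Weekly profile table; defaults to the training profiles'
#'   scores.
#' @param ... Unused.
#' @return Score table as [fifa_assign()].
#' @export
predict.fifa <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$scores)
  fifa_assign(newdata, object)
}

#' @export
fitted.fifa <- function(object, ...) object$scores$total

#' @export
plot.fifa <- function(x, ...) {
  plot(x$roc, main = sprintf("FIFA score vs hospital mortality (AUC %.3f)",
                             x$roc$auc), ...)
}
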