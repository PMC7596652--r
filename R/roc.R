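#' Rank-based ROC analysis of a scalar predictor
#'
#' Computes the area under the ROC curve as the Mann-Whitney probability that
#' a randomly chosen case outranks a randomly chosen control, with tied
#' case-control pairs counted one half (midranks). For
#' \code{direction = "negative"} (smaller values indicate the event) the
#' analysis runs on the negated predictor, so the reported AUC is always the
#' discrimination achieved in the stated risk direction.
#'
#' The confidence interval uses the Hanley-McNeil standard error with a
#' normal approximation by default, clipped to [0, 1]; \code{ci_method =
#' "delong"} switches to the DeLong placement-value variance. A constant
#' predictor yields AUC 0.5 with the \code{degenerate} flag set.
#'
#' @param values Numeric predictor (one value per patient).
#' @param outcomes Logical (or 0/1) event indicator, same length.
#' @param direction \code{"positive"} if larger values indicate the event,
#'   \code{"negative"} otherwise.
#' @param conf_level Confidence level for the AUC interval.
#' @param ci_method \code{"hanley"} (default) or \code{"delong"}.
#' @return Object of class \code{"roc_analysis"}: \code{auc}, \code{se},
#'   \code{ci_low}, \code{ci_high}, \code{n_cases}, \code{n_controls},
#'   \code{direction}, \code{degenerate}, and \code{curve} (data frame of
#'   \code{fpr}, \code{tpr} from (0,0) to (1,1)).
#' @references Hanley JA, McNeil BJ (1982) The meaning and use of the area
#'   under a receiver operating characteristic (ROC) curve. Radiology 143.
#' @export
#' @examples
#' auc_rank(c(1, 2, 5, 7, 7, 9), c(0, 0, 0, 1, 0, 1), "positive")
auc_rank <- function(values, outcomes, direction = "positive",
                     conf_level = 0.95, ci_method = c("hanley", "delong")) {
  ci_method <- match.arg(ci_method)
  check_direction(direction)
  dat <- roc_data(values, outcomes, direction)
  x <- dat$x
  y <- dat$y
  n1 <- sum(y)
  n0 <- sum(!y)

  r <- rank(x, ties.method = "average")
  auc <- (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  degenerate <- length(unique(x)) == 1L

  if (ci_method == "hanley") {
    q1 <- auc / (2 - auc)
    q2 <- 2 * auc^2 / (1 + auc)
    se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                  (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  } else {
    # DeLong: placement values of cases among controls and vice versa
    xc <- x[y]
    xk <- x[!y]
    v10 <- vapply(xc, function(v) mean((xk < v) + 0.5 * (xk == v)), 0)
    v01 <- vapply(xk, function(v) mean((xc > v) + 0.5 * (xc == v)), 0)
    se <- sqrt(stats::var(v10) / n1 + stats::var(v01) / n0)
    if (!is.finite(se)) se <- 0
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(
    auc = auc, se = se,
    ci_low = max(0, auc - z * se), ci_high = min(1, auc + z * se),
    conf_level = conf_level, ci_method = ci_method,
    n_cases = n1, n_controls = n0,
    direction = direction, degenerate = degenerate,
    curve = roc_curve(values, outcomes, direction)
  ), class = "roc_analysis")
}

#' Empirical ROC curve
#'
#' Sweeps every threshold of the predictor and returns the operating points
#' (1 - specificity, sensitivity), from (0, 0) to (1, 1), both coordinates
#' non-decreasing. The trapezoidal area under this curve equals the
#' midrank AUC of [auc_rank()].
#'
#' @inheritParams auc_rank
#' @return Data frame with columns \code{fpr} and \code{tpr}.
#' @export
roc_curve <- function(values, outcomes, direction = "positive") {
  check_direction(direction)
  dat <- roc_data(values, outcomes, direction)
  x <- dat$x
  y <- dat$y
  n1 <- sum(y)
  n0 <- sum(!y)
  ord <- order(x, decreasing = TRUE)        # call event when x >= threshold
  xs <- x[ord]
  ys <- y[ord]
  last <- cumsum(rle(xs)$lengths)           # last row of each distinct value
  tpr <- cumsum(ys)[last] / n1
  fpr <- cumsum(!ys)[last] / n0
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Youden-index threshold for a scalar predictor
#'
#' Scans every candidate cutoff — the midpoints between consecutive distinct
#' predictor values, plus -Inf/+Inf sentinels — and returns the one
#' maximising the Youden index J = sensitivity + specificity - 1. The
#' classification rule is strict: with \code{direction = "positive"} a
#' patient is called an event when the value exceeds the cutoff; with
#' \code{"negative"}, when it falls below. A value exactly at the cutoff is
#' a non-event (midpoint cutoffs never coincide with continuous data; ties
#' on discrete data behave predictably).
#'
#' Ties in J are broken in favour of the higher sensitivity (a frailty
#' screen should favour detection), then the smaller cutoff.
#'
#' @inheritParams auc_rank
#' @param parameter Optional parameter name stored in the result.
#' @return Object of class \code{"threshold_spec"}: \code{parameter},
#'   \code{direction}, \code{cutoff}, \code{j_value}, \code{sensitivity},
#'   \code{specificity}.
#' @export
#' @examples
#' youden_threshold(c(1, 2, 3, 4, 5), c(0, 0, 0, 1, 1), "positive")
youden_threshold <- function(values, outcomes, direction = "positive",
                             parameter = NA_character_) {
  check_direction(direction)
  dat <- roc_data(values, outcomes, direction = "positive", negate = FALSE)
  x <- dat$x
  y <- dat$y
  n1 <- sum(y)
  n0 <- sum(!y)
  ord <- order(x)
  xs <- x[ord]
  ys <- y[ord]
  last <- cumsum(rle(xs)$lengths)           # last row of each distinct value
  v <- xs[last]
  k <- length(v)
  cand <- if (k > 1L) c(-Inf, (v[-k] + v[-1]) / 2, Inf) else c(-Inf, Inf)
  # cases/controls at or below each distinct value
  c1 <- cumsum(ys)[last]
  c0 <- cumsum(!ys)[last]
  below1 <- c(0L, c1)   # counts with value < candidate (strictly)
  below0 <- c(0L, c0)
  if (direction == "positive") {
    sens_cnt <- n1 - below1         # event called when value > cutoff
    spec_cnt <- below0
  } else {
    sens_cnt <- below1              # event called when value < cutoff
    spec_cnt <- n0 - below0
  }
  # select on integer-scaled J so exactly-tied cutoffs are true ties
  j_scaled <- sens_cnt * n0 + spec_cnt * n1 - n1 * n0
  best <- order(-j_scaled, -sens_cnt, cand)[1L]
  sens <- sens_cnt[best] / n1
  spec <- spec_cnt[best] / n0
  structure(list(parameter = parameter, direction = direction,
                 cutoff = cand[best], j_value = sens + spec - 1,
                 sensitivity = sens, specificity = spec,
                 n_cases = n1, n_controls = n0),
            class = "threshold_spec")
}

# internal: validated (predictor, event) pairs; negates for direction, drops
# missing predictor values
roc_data <- function(values, outcomes, direction, negate = TRUE) {
  if (length(values) != length(outcomes)) {
    stop("values and outcomes must have equal length", call. = FALSE)
  }
  y <- as.logical(outcomes)
  if (anyNA(y)) stop("outcomes must not be missing", call. = FALSE)
  ok <- !is.na(values)
  x <- as.numeric(values[ok])
  y <- y[ok]
  if (sum(y) == 0L || sum(!y) == 0L) {
    stop("AUC undefined: need at least one case and one control",
         call. = FALSE)
  }
  if (negate && direction == "negative") x <- -x
  list(x = x, y = y)
}

#' @export
print.roc_analysis <- function(x, digits = 3, ...) {
  cat(sprintf("ROC analysis (%s direction): AUC %.*f, %d%% CI %.*f-%.*f\n",
              x$direction, digits, x$auc, round(100 * x$conf_level),
              digits, x$ci_low, digits, x$ci_high))
  cat(sprintf("  %d case(s) vs %d control(s); SE %.*f (%s)%s\n",
              x$n_cases, x$n_controls, digits, x$se, x$ci_method,
              if (x$degenerate) "; constant predictor (degenerate CI)" else ""))
  invisible(x)
}

#' @export
print.threshold_spec <- function(x, digits = 3, ...) {
  lab <- if (is.na(x$parameter)) "predictor" else x$parameter
  rule <- if (x$direction == "positive") ">" else "<"
  cat(sprintf("Youden threshold for %s: event when value %s %.4g\n",
              lab, rule, x$cutoff))
  cat(sprintf("  J = %.*f (sensitivity %.*f, specificity %.*f)\n",
              digits, x$j_value, digits, x$sensitivity,
              digits, x$specificity))
  invisible(x)
}

#' @export
plot.roc_analysis <- function(x, add = FALSE, col = "black", ...) {
  if (!add) {
    graphics::plot(x$curve$fpr, x$curve$tpr, type = "l", col = col,
                   xlab = "1 - specificity", ylab = "Sensitivity",
                   xlim = c(0, 1), ylim = c(0, 1), ...)
    graphics::abline(0, 1, lty = 3, col = "grey60")
  } else {
    graphics::lines(x$curve$fpr, x$curve$tpr, col = col, ...)
  }
  invisible(x)
}
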