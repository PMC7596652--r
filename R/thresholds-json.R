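#' Write or read derived category thresholds as JSON
#'
#' Serialises a set of [youden_threshold()] specs (for example
#' \code{fit$thresholds} of a [fifa_fit()]) as a JSON array of objects with
#' fields \code{category}, \code{parameter}, \code{direction},
#' \code{cutoff}, \code{j_value}, \code{sensitivity}, \code{specificity},
#' so a score derived on one cohort can be applied to another.
#'
#' @param thresholds Named list of threshold specs.
#' @param path Output path.
#' @return \code{path} invisibly; the reader returns the named list of
#'   specs.
#' @export
write_thresholds_json <- function(thresholds, path) {
  recs <- lapply(names(thresholds), function(nm) {
    th <- thresholds[[nm]]
    list(category = nm, parameter = th$parameter,
         direction = th$direction, cutoff = th$cutoff,
         j_value = th$j_value, sensitivity = th$sensitivity,
         specificity = th$specificity)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_thresholds_json
#' @export
read_thresholds_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(recs, function(r) {
    structure(list(parameter = r$parameter,
                   direction = check_direction(r$direction),
                   cutoff = as.numeric(r$cutoff),
                   j_value = as.numeric(r$j_value),
                   sensitivity = as.numeric(r$sensitivity),
                   specificity = as.numeric(r$specificity)),
              class = "threshold_spec")
  })
  names(out) <- vapply(recs, function(r) r$category, "")
  out
}
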