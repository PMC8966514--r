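#' Group-wise summary of a metric table
#'
#' Summarizes one numeric metric over experimental groups (typically dose
#' and fixation-time labels) with the statistics reported for foci data:
#' arithmetic mean, median, 25th and 75th percentiles
#' (linear-interpolation quantile definition, R type 7) and the group
#' size. Missing metric values are dropped with a warning; empty groups
#' are omitted.
#'
#' @param table A data frame of per-nucleus or per-cluster metrics.
#' @param metric Column to summarize (tidy-eval).
#' @param ... Grouping columns (tidy-eval); omit for a single overall row.
#'
#' @return A tibble with one row per group: the group keys, `mean`,
#'   `median`, `p25`, `p75`, `n`.
#' @export
#' @examples
#' tab <- tibble::tibble(dose = rep(c("0Gy", "2Gy"), each = 5),
#'                       foci = c(1:5, 11:15))
#' summarize_metrics(tab, foci, dose)
summarize_metrics <- function(table, metric, ...) {
  metric <- rlang::enquo(metric)
  keys <- rlang::enquos(...)
  vals <- rlang::eval_tidy(metric, table)
  if (!is.numeric(vals)) abort("`metric` must be a numeric column.")
  if (anyNA(vals))
    warn(sprintf("dropping %d missing values of the metric.",
                 sum(is.na(vals))))
  grouped <- group_by(filter(table, !is.na(!!metric)), !!!keys)
  out <- summarise(grouped,
                   mean = mean(!!metric),
                   median = median(!!metric),
                   p25 = quantile(!!metric, 0.25, names = FALSE, type = 7),
                   p75 = quantile(!!metric, 0.75, names = FALSE, type = 7),
                   n = n(),
                   .groups = "drop")
  out
}

#' Export observations in long format for distribution plots
#'
#' One row per observation with its group labels — the layout violin and
#' box plots are drawn from. The file round-trips losslessly through
#' [readr::read_csv()] for finite doubles.
#'
#' @param table A data frame of metrics.
#' @param metric Column to export (tidy-eval).
#' @param ... Grouping columns kept alongside the value.
#' @param path CSV output path, or `NULL` to skip writing.
#'
#' @return The long-format tibble (`value` plus the group columns),
#'   invisibly when `path` is given.
#' @export
export_distribution <- function(table, metric, ..., path = NULL) {
  metric <- rlang::enquo(metric)
  keys <- rlang::enquos(...)
  out <- transmute(table, !!!keys, value = !!metric)
  if (!is.null(path)) {
    readr::write_csv(out, path)
    return(invisible(out))
  }
  out
}

#' @importFrom dplyr transmute
NULL
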