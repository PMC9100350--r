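#' Summary statistics of one replicate series
#'
#' Arithmetic mean and sample (n − 1) standard deviation; with a single
#' reading the SD is 0 by convention.
#'
#' @param values Numeric vector of replicate readings, at least one.
#' @return List with `mean`, `sd`, `n`.
#' @examples
#' series_stats(c(8, 12))
#' @export
series_stats <- function(values) {
  if (length(values) < 1L || anyNA(values)) {
    abort("need at least one non-missing reading.", class = "skincap_range_error")
  }
  list(mean = mean(values),
       sd = if (length(values) > 1L) stats::sd(values) else 0,
       n = length(values))
}

#' Coefficient of variation of a replicate series
#'
#' `100 * sd / mean`, the standard repeatability index for an instrument:
#' the ratio of the sample standard deviation to the mean reading, as a
#' percentage. Scale-invariant (unchanged under multiplying every reading
#' by a positive constant). Requires at least two readings and a positive
#' mean.
#'
#' @param values Numeric vector of replicate readings.
#' @return CV in percent.
#' @examples
#' cv_percent(c(8, 12))  # ~28.3 %
#' @export
cv_percent <- function(values) {
  if (length(values) < 2L) {
    abort("CV is undefined for fewer than 2 readings.",
          class = "skincap_range_error")
  }
  m <- mean(values)
  if (m <= 0) {
    abort("CV is undefined for a non-positive mean.",
          class = "skincap_range_error")
  }
  100 * stats::sd(values) / m
}

#' Before/after change of a measurement series
#'
#' @param before,after Numeric vectors of replicate readings;
#'   `mean(before)` must be positive.
#' @return List with `delta` (`mean(after) - mean(before)`) and `delta_pct`
#'   (the same as a percentage of the baseline mean).
#' @examples
#' tewl_change(before = c(12, 12, 12), after = c(9, 9, 9))
#' @export
tewl_change <- function(before, after) {
  b <- series_stats(before); a <- series_stats(after)
  if (b$mean <= 0) {
    abort("baseline mean must be positive.", class = "skincap_range_error")
  }
  delta <- a$mean - b$mean
  list(delta = delta, delta_pct = 100 * delta / b$mean)
}

#' Per-series summary of a measurement table
#'
#' One row per (site, timepoint, instrument) series with mean, sample SD,
#' replicate count and CV (CV is `NA` for single-reading series).
#'
#' @param measurements Tibble in the [read_measurements()] schema.
#' @return Tibble with columns `site_id`, `timepoint`, `instrument`,
#'   `mean`, `sd`, `n`, `cv`.
#' @export
tewl_summary <- function(measurements) {
  measurements |>
    dplyr::group_by(.data$site_id, .data$timepoint, .data$instrument) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = if (dplyr::n() > 1L) stats::sd(.data$value) else 0,
                     n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(cv = dplyr::if_else(.data$n > 1L & .data$mean > 0,
                                      100 * .data$sd / .data$mean,
                                      NA_real_))
}

#' Full site report with before/after deltas
#'
#' Summarises every series and, within each (site, instrument) pair,
#' subtracts the baseline timepoint's mean. Sites or instruments with no
#' baseline series get `NA` deltas and a warning.
#'
#' @param measurements Tibble in the [read_measurements()] schema.
#' @param baseline Baseline timepoint label. Default `"before"`.
#' @return Tibble with one row per (site, timepoint, instrument):
#'   `mean`, `sd`, `n`, `cv`, `delta`, `delta_pct` (deltas vs baseline;
#'   0 at the baseline itself).
#' @export
site_report <- function(measurements, baseline = "before") {
  summ <- tewl_summary(measurements)
  out <- summ |>
    dplyr::group_by(.data$site_id, .data$instrument) |>
    dplyr::mutate(.base = {
      idx <- which(.data$timepoint == baseline)
      if (length(idx) == 1L) .data$mean[idx] else NA_real_
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(delta = .data$mean - .data$.base,
                  delta_pct = 100 * .data$delta / .data$.base) |>
    dplyr::select(-".base")
  if (anyNA(out$delta)) {
    missing <- unique(out$site_id[is.na(out$delta)])
    warn(sprintf("no '%s' baseline for site(s): %s; deltas set to NA.",
                 baseline, paste(missing, collapse = ", ")))
  }
  out
}
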