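#' Grey-level to permittivity calibration
#'
#' The imaging die reports an 8-bit grey level per pixel that is monotone in
#' the local relative permittivity of whatever touches it. The device's
#' internal calibration is proprietary, so an affine map is used, anchored by
#' default at physically meaningful endpoints: grey 0 corresponds to air
#' (relative permittivity 1) and grey 255 to liquid water at room temperature
#' (relative permittivity 81). Override the anchors if a device-specific
#' calibration is available; every downstream statistic is reported on the
#' calibrated (permittivity) scale.
#'
#' @param grey_low,grey_high Grey-level anchors, `grey_low < grey_high`.
#' @param eps_low,eps_high Permittivity values at the anchors,
#'   `eps_low < eps_high`.
#' @return A `calibration` object (named list).
#' @export
calibration <- function(grey_low = 0, grey_high = 255,
                        eps_low = 1, eps_high = 81) {
  if (grey_low >= grey_high || eps_low >= eps_high) {
    abort("calibration anchors must satisfy grey_low < grey_high and eps_low < eps_high.",
          class = "skincap_param_error")
  }
  structure(list(grey_low = grey_low, grey_high = grey_high,
                 eps_low = eps_low, eps_high = eps_high),
            class = "calibration")
}

# identity map on the grey scale, for analyses in raw grey levels
identity_calibration <- function() calibration(0, 255, 0, 255)

#' Map grey levels to the permittivity scale
#'
#' Applies the affine map sending `grey_low -> eps_low` and
#' `grey_high -> eps_high` elementwise, without clipping.
#'
#' @param img A [capacitive_image()] or numeric matrix.
#' @param cal A [calibration()].
#' @return A numeric matrix of permittivity values, same shape as `img`.
#' @export
grey_to_permittivity <- function(img, cal = calibration()) {
  stopifnot(inherits(cal, "calibration"))
  px <- as_pixel_matrix(img)
  cal$eps_low + (px - cal$grey_low) *
    (cal$eps_high - cal$eps_low) / (cal$grey_high - cal$grey_low)
}

#' Permittivity statistics and histogram over an ROI
#'
#' Maps the ROI pixels to the permittivity scale and returns their mean,
#' sample standard deviation and an equal-width histogram over
#' `[eps_low, eps_high]`. All bins are left-closed, right-open except the
#' last, which is closed on both sides, so counts always sum to the number
#' of ROI pixels; values falling outside the calibration range (possible
#' with non-anchoring calibrations) are counted in the first or last bin.
#'
#' @param img A [capacitive_image()].
#' @param roi A [roi_rect()] inside `img`.
#' @param cal A [calibration()].
#' @param n_bins Number of histogram bins, at least 1. Default 32.
#' @return A list with `mean`, `sd`, `n`, and `histogram` (tibble with
#'   `bin_low`, `bin_high`, `count`).
#' @export
roi_stats <- function(img, roi, cal = calibration(), n_bins = 32L) {
  stopifnot(is_capacitive_image(img) || is.matrix(img))
  if (n_bins < 1L) {
    abort("`n_bins` must be at least 1.", class = "skincap_param_error")
  }
  if (is_capacitive_image(img)) {
    vals <- grey_to_permittivity(crop_image(img, roi), cal)
  } else {
    check_roi_inside(roi, img)
    vals <- grey_to_permittivity(
      img[roi$y + seq_len(roi$h), roi$x + seq_len(roi$w), drop = FALSE], cal)
  }
  vals <- as.vector(vals)
  edges <- seq(cal$eps_low, cal$eps_high, length.out = n_bins + 1L)
  idx <- findInterval(vals, edges, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), n_bins)   # out-of-range values into edge bins
  counts <- tabulate(idx, nbins = n_bins)
  list(mean = mean(vals),
       sd = if (length(vals) > 1L) stats::sd(vals) else 0,
       n = length(vals),
       histogram = tibble::tibble(bin_low = edges[-(n_bins + 1L)],
                                  bin_high = edges[-1L],
                                  count = counts))
}

#' Hydration change versus baseline
#'
#' Given per-timepoint mean permittivities (optionally per site), subtracts
#' the baseline timepoint's mean within each group: positive deltas mean the
#' site got wetter after application.
#'
#' @param stats A tibble with columns `timepoint` and `mean`; any other
#'   columns (e.g. `site_id`) define groups within which the baseline is
#'   subtracted. A named numeric vector (timepoint -> mean) is also accepted.
#' @param baseline Label of the baseline timepoint. Default `"before"`.
#' @return A tibble with the input columns plus `delta` (`mean` minus the
#'   group's baseline mean; 0 at the baseline itself).
#' @examples
#' hydration_change(c(before = 10, `1h` = 14, `2h` = 13))
#' @export
hydration_change <- function(stats, baseline = "before") {
  if (is.numeric(stats) && !is.null(names(stats))) {
    stats <- tibble::tibble(timepoint = names(stats), mean = unname(stats))
  }
  stopifnot(is.data.frame(stats), all(c("timepoint", "mean") %in% names(stats)))
  groups <- setdiff(names(stats), c("timepoint", "mean", "sd", "n", "delta"))
  out <- stats |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::mutate(delta = {
      base_idx <- which(.data$timepoint == baseline)
      if (length(base_idx) != 1L) {
        abort(sprintf("baseline timepoint '%s' missing (or duplicated) in a group.",
                      baseline), class = "skincap_baseline_error")
      }
      .data$mean - .data$mean[base_idx]
    }) |>
    dplyr::ungroup()
  tibble::as_tibble(out)
}

#' Ratio of hydration to trans-epidermal water loss
#'
#' The mean ROI permittivity divided by the mean TEWL of the same site and
#' timepoint. Because an occlusive film raises skin water content while
#' suppressing water flux, the ratio amplifies the product effect in a
#' single index; it is homogeneous of degree zero (common rescaling of both
#' inputs leaves it unchanged).
#'
#' @param eps_mean Mean permittivity (dimensionless), or a vector thereof.
#' @param tewl_mean Mean TEWL (g·m⁻²·h⁻¹), strictly positive.
#' @return `eps_mean / tewl_mean`.
#' @export
hydration_tewl_ratio <- function(eps_mean, tewl_mean) {
  if (any(tewl_mean <= 0)) {
    abort("`tewl_mean` must be strictly positive.", class = "skincap_range_error")
  }
  eps_mean / tewl_mean
}
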