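#' Capacitive skin image
#'
#' A capacitive image is an 8-bit grey-level grid acquired by a
#' fingerprint-sensor die used as a skin permittivity imager: brighter pixels
#' mean higher pixel capacitance, i.e. higher relative permittivity, i.e.
#' more water in the stratum corneum. Pixels are stored as an integer matrix
#' (rows = y, columns = x, origin top-left); the physical pixel pitch is
#' carried as metadata only and never enters any computation.
#'
#' @param pixels Numeric or integer matrix with values in `[0, 2^bit_depth - 1]`.
#' @param pixel_pitch Pixel pitch in micrometres (metadata only). Default 50.
#' @param bit_depth Grey-level bit depth. Default 8.
#'
#' @return An object of class `capacitive_image`: the integer pixel matrix
#'   with `pixel_pitch` and `bit_depth` attributes.
#' @examples
#' img <- capacitive_image(matrix(0:255, 16, 16))
#' dim(img)
#' @export
capacitive_image <- function(pixels, pixel_pitch = 50, bit_depth = 8L) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort("`pixels` must be a numeric matrix.", class = "skincap_format_error")
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    abort("image must have at least one row and one column.",
          class = "skincap_format_error")
  }
  if (!is.numeric(pixel_pitch) || length(pixel_pitch) != 1L || pixel_pitch <= 0) {
    abort("`pixel_pitch` must be a single positive number.",
          class = "skincap_format_error")
  }
  maxval <- 2^bit_depth - 1
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > maxval)) {
    abort(sprintf("pixel values must lie in [0, %d].", maxval),
          class = "skincap_range_error")
  }
  if (any(pixels != round(pixels))) {
    abort("pixel values must be integers.", class = "skincap_range_error")
  }
  structure(
    matrix(as.integer(round(pixels)), nrow(pixels), ncol(pixels)),
    pixel_pitch = pixel_pitch,
    bit_depth = as.integer(bit_depth),
    class = c("capacitive_image", "matrix", "array")
  )
}

#' @export
print.capacitive_image <- function(x, ...) {
  cat(sprintf("<capacitive_image> %d x %d px, %d-bit, pitch %g um\n",
              nrow(x), ncol(x), attr(x, "bit_depth"), attr(x, "pixel_pitch")))
  cat(sprintf("  grey levels: min %d, max %d, mean %.1f\n",
              min(x), max(x), mean(x)))
  invisible(x)
}

#' @export
as.matrix.capacitive_image <- function(x, ...) {
  matrix(as.integer(x), nrow(x), ncol(x))
}

is_capacitive_image <- function(x) inherits(x, "capacitive_image")

as_pixel_matrix <- function(x) {
  if (is_capacitive_image(x)) return(matrix(as.double(x), nrow(x), ncol(x)))
  if (is.matrix(x) && is.numeric(x)) return(matrix(as.double(x), nrow(x), ncol(x)))
  abort("expected a capacitive_image or numeric matrix.",
        class = "skincap_format_error")
}

#' Rectangular region of interest
#'
#' Image coordinates are 0-based with `x` the column and `y` the row of the
#' top-left corner, so the rectangle covers the half-open pixel ranges
#' `[x, x + w)` horizontally and `[y, y + h)` vertically.
#'
#' @param x,y Top-left corner, 0-based pixels.
#' @param w,h Width and height in pixels (each at least 1).
#' @return A `roi_rect` object (named list).
#' @examples
#' roi_rect(10, 20, 64, 64)
#' @export
roi_rect <- function(x, y, w, h) {
  vals <- c(x = x, y = y, w = w, h = h)
  if (any(vals != round(vals)) || x < 0 || y < 0 || w < 1 || h < 1) {
    abort("roi_rect needs integer x, y >= 0 and w, h >= 1.",
          class = "skincap_roi_error")
  }
  structure(list(x = as.integer(x), y = as.integer(y),
                 w = as.integer(w), h = as.integer(h)),
            class = "roi_rect")
}

#' @export
print.roi_rect <- function(x, ...) {
  cat(sprintf("<roi_rect> x=%d y=%d w=%d h=%d\n", x$x, x$y, x$w, x$h))
  invisible(x)
}

#' @export
format.roi_rect <- function(x, ...) sprintf("%d,%d,%d,%d", x$x, x$y, x$w, x$h)

check_roi_inside <- function(roi, img) {
  if (roi$x + roi$w > ncol(img) || roi$y + roi$h > nrow(img)) {
    abort(sprintf("ROI [%s] extends outside the %d x %d image.",
                  format(roi), nrow(img), ncol(img)),
          class = "skincap_roi_error")
  }
  invisible(TRUE)
}

#' Crop a rectangular region out of an image
#'
#' @param img A [capacitive_image()].
#' @param roi A [roi_rect()] lying fully inside `img`.
#' @return A `capacitive_image` of size `h` x `w`.
#' @export
crop_image <- function(img, roi) {
  stopifnot(is_capacitive_image(img), inherits(roi, "roi_rect"))
  check_roi_inside(roi, img)
  px <- as.matrix(img)[roi$y + seq_len(roi$h), roi$x + seq_len(roi$w), drop = FALSE]
  capacitive_image(px, pixel_pitch = attr(img, "pixel_pitch"),
                   bit_depth = attr(img, "bit_depth"))
}
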