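#' Read a capacitive image from PNG or CSV
#'
#' PNG files must be single-channel 8-bit greyscale. CSV grids are
#' comma-separated bare integers, no header, row-major with the top image row
#' first. Values are preserved bit-exactly in both directions.
#'
#' @param path File to read.
#' @param fmt `"png"` or `"csv"`; default guessed from the file extension.
#' @param pixel_pitch Pixel pitch metadata in micrometres (not stored by
#'   either format). Default 50.
#' @return A [capacitive_image()].
#' @seealso [write_image()]
#' @export
read_image <- function(path, fmt = c("auto", "png", "csv"), pixel_pitch = 50) {
  fmt <- match.arg(fmt)
  if (fmt == "auto") fmt <- guess_image_fmt(path)
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "skincap_io_error")
  }
  px <- switch(fmt, png = read_image_png(path), csv = read_image_csv(path))
  capacitive_image(px, pixel_pitch = pixel_pitch)
}

guess_image_fmt <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("png", "csv")) {
    abort(sprintf("cannot guess image format from extension '.%s'.", ext),
          class = "skincap_format_error")
  }
  ext
}

read_image_png <- function(path) {
  raw <- png::readPNG(path, info = TRUE)
  info <- attr(raw, "info")
  if (!is.null(info) && !is.null(info$bit.depth) && info$bit.depth > 8L) {
    abort(sprintf("PNG has bit depth %d; only 8-bit greyscale is supported.",
                  info$bit.depth), class = "skincap_format_error")
  }
  if (length(dim(raw)) == 3L) {
    abort(sprintf("PNG has %d channels; only single-channel greyscale is supported.",
                  dim(raw)[3]), class = "skincap_format_error")
  }
  round(raw * 255)
}

read_image_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    abort("CSV image file is empty.", class = "skincap_parse_error")
  }
  rows <- strsplit(lines, ",", fixed = TRUE)
  widths <- lengths(rows)
  if (length(unique(widths)) != 1L) {
    abort("ragged CSV image: rows have differing numbers of values.",
          class = "skincap_parse_error")
  }
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  if (anyNA(vals)) {
    abort("non-numeric entry in CSV image.", class = "skincap_parse_error")
  }
  matrix(vals, nrow = length(rows), ncol = widths[1], byrow = TRUE)
}

#' Write a capacitive image to PNG or CSV
#'
#' The written file reads back bit-exactly with [read_image()].
#'
#' @param img A [capacitive_image()].
#' @param path Destination file.
#' @param fmt `"png"` or `"csv"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, fmt = c("auto", "png", "csv")) {
  stopifnot(is_capacitive_image(img))
  fmt <- match.arg(fmt)
  if (fmt == "auto") fmt <- guess_image_fmt(path)
  px <- as.matrix(img)
  if (fmt == "png") {
    png::writePNG(px / 255, target = path)
  } else {
    writeLines(apply(px, 1L, paste, collapse = ","), con = path)
  }
  invisible(path)
}

measurement_cols <- c("site_id", "timepoint", "instrument", "replicate", "value")

#' Read a table of repeated measurements
#'
#' Reads a CSV with the header `site_id,timepoint,instrument,replicate,value`,
#' one row per replicate reading (TEWL in g·m⁻²·h⁻¹, or dimensionless
#' permittivity). Replicate order within each series is preserved.
#'
#' @param path CSV file.
#' @return A tibble with one row per reading and the five schema columns;
#'   `value` numeric, `replicate` integer.
#' @seealso [nest_series()] to collapse to one row per measurement series.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "skincap_io_error")
  }
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  show_col_types = FALSE))
  missing <- setdiff(measurement_cols, header)
  if (length(missing) > 0L) {
    abort(sprintf("measurement CSV is missing column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "skincap_schema_error")
  }
  df <- readr::read_csv(path, col_types = readr::cols(
    site_id = readr::col_character(),
    timepoint = readr::col_character(),
    instrument = readr::col_character(),
    replicate = readr::col_integer(),
    value = readr::col_double()
  ))
  if (nrow(df) > 0L && anyNA(df$value)) {
    abort("non-numeric or missing entries in `value`.",
          class = "skincap_parse_error")
  }
  if (nrow(df) > 0L && any(df$value <= 0)) {
    abort("measurement values must be positive.", class = "skincap_range_error")
  }
  tibble::as_tibble(df[measurement_cols])
}

#' Write a measurement table to CSV
#'
#' @param measurements Tibble in the [read_measurements()] schema.
#' @param path Destination CSV file.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  stopifnot(all(measurement_cols %in% names(measurements)))
  readr::write_csv(measurements[measurement_cols], path)
  invisible(path)
}

#' Nest a measurement table into one row per series
#'
#' Groups by (site_id, timepoint, instrument) and collapses the replicate
#' readings, in replicate order, into a list-column `values`.
#'
#' @param measurements Tibble in the [read_measurements()] schema.
#' @return Tibble with columns `site_id`, `timepoint`, `instrument`,
#'   `values` (list of numeric vectors) and `n`.
#' @export
nest_series <- function(measurements) {
  measurements |>
    dplyr::arrange(.data$site_id, .data$timepoint, .data$instrument,
                   .data$replicate) |>
    dplyr::group_by(.data$site_id, .data$timepoint, .data$instrument) |>
    dplyr::summarise(values = list(.data$value), n = dplyr::n(),
                     .groups = "drop")
}
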