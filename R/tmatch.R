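#' @name tmatch
#' @title Template matching for ROI relocation
#'
#' @description
#' A region of interest selected in one capture of a skin site is found
#' again in later captures by exhaustive sliding-window scoring: the
#' template `T` is placed at every valid offset `(x, y)` of the target image
#' `I` and a score `R(x, y)` is computed from the overlapping pixels. Six
#' scoring functions are provided, in two families:
#'
#' * difference methods — `SqDiff` (sum of squared differences) and
#'   `SqDiff_Normed`; the best match is the score **minimum**;
#' * correlation methods — `CCorr`, `CCorr_Normed` (raw cross-correlation),
#'   `CCoeff`, `CCoeff_Normed` (cross-correlation of mean-subtracted
#'   template and window, the window mean recomputed at every placement);
#'   the best match is the score **maximum**.
#'
#' By default the classical definitions are used: correlation scores sum
#' plain products and the `_Normed` variants divide by the square root of
#' the product of template and window energies, so `CCoeff_Normed` is the
#' Pearson correlation of template and window and lies in `[-1, 1]`.
#' `literal = TRUE` instead evaluates a printed variant of these formulas in
#' which each product term is squared and the normalising denominators are
#' used without the square root; both variants share every other convention
#' and are exposed so results computed either way can be reproduced.
#'
#' Surfaces contain valid placements only (no padding): for an `H x W` image
#' and `h x w` template the surface is `(H - h + 1) x (W - w + 1)`, and
#' surface cell `(x, y)` (0-based) scores the window whose top-left pixel is
#' image column `x`, row `y`.
NULL

tm_methods <- c("SqDiff", "SqDiff_Normed", "CCorr", "CCorr_Normed",
                "CCoeff", "CCoeff_Normed")

match_method <- function(method) {
  idx <- match(tolower(method), tolower(tm_methods))
  if (is.na(idx)) {
    abort(sprintf("unknown method '%s'; choose one of: %s",
                  method, paste(tm_methods, collapse = ", ")),
          class = "skincap_param_error")
  }
  tm_methods[idx]
}

is_min_method <- function(method) method %in% c("SqDiff", "SqDiff_Normed")

#' Compute a template-matching score surface
#'
#' Scores every valid placement of `template` over `image` with one of the
#' six methods described in [tmatch]. Pixels are treated as real numbers;
#' all arithmetic is double precision.
#'
#' @param image Target image: a [capacitive_image()] or numeric matrix.
#' @param template The ROI crop to search for; dimensions must not exceed
#'   the image's.
#' @param method One of `"SqDiff"`, `"SqDiff_Normed"`, `"CCorr"`,
#'   `"CCorr_Normed"`, `"CCoeff"`, `"CCoeff_Normed"` (case-insensitive).
#' @param literal If `TRUE`, evaluate the squared-product / root-free
#'   variant of the formulas (see [tmatch]). Default `FALSE` (classical
#'   definitions).
#' @return A `match_surface` object: list with `scores` (the
#'   `(H-h+1) x (W-w+1)` matrix), `method`, `literal`, `template_dim`.
#' @examples
#' img <- generate_texture(c(32, 32), texture_params(seed = 7))
#' tpl <- crop_image(img, roi_rect(5, 9, 8, 8))
#' s <- match_surface(img, tpl, "CCorr_Normed")
#' best_match(s)
#' @export
match_surface <- function(image, template, method = "CCorr_Normed",
                          literal = FALSE) {
  method <- match_method(method)
  I <- as_pixel_matrix(image)
  T <- as_pixel_matrix(template)
  if (nrow(T) > nrow(I) || ncol(T) > ncol(I)) {
    abort("template dimensions exceed image dimensions.",
          class = "skincap_size_error")
  }
  nT <- length(T)
  Tsum <- sum(T)
  Tss <- sum(T^2)
  Tc <- T - Tsum / nT          # mean-subtracted template
  Tpss <- sum(Tc^2)

  if (method %in% c("SqDiff_Normed", "CCorr_Normed") && Tss == 0) {
    abort("all-zero template is degenerate under a normalised method.",
          class = "skincap_degenerate_error")
  }
  if (method == "CCoeff_Normed" && Tpss == 0) {
    abort("constant template is degenerate under CCoeff_Normed.",
          class = "skincap_degenerate_error")
  }

  ones <- matrix(1, nrow(T), ncol(T))
  S1 <- cpp_xcorr(I, ones)       # window sums
  S2 <- cpp_xcorr(I^2, ones)     # window sums of squares
  Ipss <- pmax(S2 - S1^2 / nT, 0)  # window centred energy (>= 0 up to roundoff)

  scores <- if (!literal) {
    C <- cpp_xcorr(I, T)
    switch(method,
      SqDiff        = Tss - 2 * C + S2,
      SqDiff_Normed = safe_div(Tss - 2 * C + S2, sqrt(Tss * S2), minimize = TRUE),
      CCorr         = C,
      CCorr_Normed  = safe_div(C, sqrt(Tss * S2), minimize = FALSE),
      CCoeff        = C - Tsum * S1 / nT,
      CCoeff_Normed = safe_div(C - Tsum * S1 / nT, sqrt(Tpss * Ipss),
                               minimize = FALSE)
    )
  } else {
    switch(method,
      SqDiff        = Tss - 2 * cpp_xcorr(I, T) + S2,
      SqDiff_Normed = safe_div(Tss - 2 * cpp_xcorr(I, T) + S2, Tss * S2,
                               minimize = TRUE),
      CCorr         = cpp_xcorr(I^2, T^2),
      CCorr_Normed  = safe_div(cpp_xcorr(I^2, T^2), Tss * S2, minimize = FALSE),
      CCoeff        = literal_ccoeff(I, Tc, S1, S2, nT),
      CCoeff_Normed = safe_div(literal_ccoeff(I, Tc, S1, S2, nT), Tpss * Ipss,
                               minimize = FALSE)
    )
  }
  # SqDiff is a sum of squares; clamp tiny negative roundoff
  if (method == "SqDiff") scores <- pmax(scores, 0)
  structure(list(scores = scores, method = method, literal = literal,
                 template_dim = dim(T)),
            class = "match_surface")
}

# Sum over the footprint of (T'(x',y') * I'(x+x',y+y'))^2, expanded so each
# placement needs only correlations against T'^2:
#   sum T'^2 (I - mu)^2 = corr(I^2, T'^2) - 2 mu corr(I, T'^2) + mu^2 sum T'^2
# with mu the window mean S1 / nT.
literal_ccoeff <- function(I, Tc, S1, S2, nT) {
  Tc2 <- Tc^2
  mu <- S1 / nT
  cpp_xcorr(I^2, Tc2) - 2 * mu * cpp_xcorr(I, Tc2) + mu^2 * sum(Tc2)
}

# division with a deterministic worst-match value where the denominator
# vanishes (featureless window): +Inf for minimised scores, 0 for maximised
safe_div <- function(num, den, minimize) {
  out <- num / den
  bad <- den == 0
  if (any(bad)) out[bad] <- if (minimize) ifelse(num[bad] == 0, 0, Inf) else 0
  out
}

#' @export
print.match_surface <- function(x, ...) {
  cat(sprintf("<match_surface> %s%s, %d x %d placements (template %d x %d)\n",
              x$method, if (x$literal) " (literal)" else "",
              nrow(x$scores), ncol(x$scores),
              x$template_dim[1], x$template_dim[2]))
  bm <- best_match(x)
  cat(sprintf("  best match at (x=%d, y=%d), score %.6g\n",
              bm$location[["x"]], bm$location[["y"]], bm$score))
  invisible(x)
}

#' Locate the best match on a score surface
#'
#' Returns the argmin for the difference methods (`SqDiff`,
#' `SqDiff_Normed`) and the argmax for the correlation methods. Ties are
#' broken deterministically by smallest `y`, then smallest `x`.
#'
#' @param surface A `match_surface` from [match_surface()].
#' @return List with `location` (named integer vector `c(x=, y=)`, 0-based
#'   top-left placement) and `score`.
#' @export
best_match <- function(surface) {
  stopifnot(inherits(surface, "match_surface"))
  sc <- surface$scores
  if (length(sc) == 0L) {
    abort("empty match surface.", class = "skincap_size_error")
  }
  ext <- if (is_min_method(surface$method)) min(sc) else max(sc)
  cand <- which(sc == ext, arr.ind = TRUE)
  pick <- cand[order(cand[, 1], cand[, 2])[1], , drop = TRUE]
  list(location = c(x = unname(pick[2]) - 1L, y = unname(pick[1]) - 1L),
       score = ext)
}

#' Relocate an ROI across a sequence of captures
#'
#' Crops `roi` out of the reference frame and finds its best-matching
#' placement in each target frame. The default method is `CCorr_Normed`,
#' which is robust to the brightness changes that hydration itself induces
#' between captures.
#'
#' @param reference The frame the ROI was drawn on.
#' @param roi A [roi_rect()] inside `reference`.
#' @param targets A list of target frames (or a single frame).
#' @param method,literal Passed to [match_surface()].
#' @return A tibble with one row per target: `target` (name or index),
#'   `x`, `y`, `w`, `h` of the relocated rectangle, and the peak `score`.
#' @examples
#' ref <- generate_texture(c(64, 64), texture_params(seed = 3))
#' tgt <- shift_and_capture(ref, dx = 5, dy = -2)
#' relocate_roi(ref, roi_rect(20, 20, 24, 24), list(tgt))
#' @export
relocate_roi <- function(reference, roi, targets, method = "CCorr_Normed",
                         literal = FALSE) {
  if (is_capacitive_image(targets) || is.matrix(targets)) targets <- list(targets)
  tpl <- crop_image(reference, roi)
  labels <- names(targets)
  if (is.null(labels)) labels <- as.character(seq_along(targets))
  purrr::map2_dfr(targets, labels, function(tgt, lab) {
    bm <- best_match(match_surface(tgt, tpl, method = method, literal = literal))
    tibble::tibble(target = lab,
                   x = bm$location[["x"]], y = bm$location[["y"]],
                   w = roi$w, h = roi$h, score = bm$score,
                   method = method)
  })
}
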