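#' Texture parameters for synthetic skin images
#'
#' Synthetic capacitive frames emulate the visual structure of real skin
#' captures: a bright plateau (hydrated stratum corneum) crossed by a network
#' of dark micro-relief lines, plus additive sensor noise. Two families of
#' roughly parallel, gently wandering anti-aliased lines at different
#' orientations reproduce the criss-cross glyphic pattern without modelling
#' skin physics.
#'
#' @param base_level Mean grey level of the plateau (0-255). Default 90:
#'   unhydrated skin images are relatively dark.
#' @param relief_contrast Depth of the micro-relief lines in grey levels.
#'   Default 60.
#' @param line_spacing Mean spacing between relief lines in pixels.
#'   Default 12.
#' @param line_angle_set Orientations of the line families in degrees.
#'   Default `c(30, 120)`.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise in
#'   grey levels. Default 0 (noise is usually added per capture, see
#'   [shift_and_capture()]).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A `texture_params` object (named list).
#' @export
texture_params <- function(base_level = 90, relief_contrast = 60,
                           line_spacing = 12, line_angle_set = c(30, 120),
                           noise_sd = 0, seed = NULL) {
  if (line_spacing < 2) {
    abort("`line_spacing` must be at least 2 pixels.", class = "skincap_param_error")
  }
  if (noise_sd < 0) {
    abort("`noise_sd` must be non-negative.", class = "skincap_param_error")
  }
  if (base_level < 0 || base_level > 255) {
    abort("`base_level` must lie in [0, 255].", class = "skincap_param_error")
  }
  structure(list(base_level = base_level, relief_contrast = relief_contrast,
                 line_spacing = line_spacing, line_angle_set = line_angle_set,
                 noise_sd = noise_sd, seed = seed),
            class = "texture_params")
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic capacitive skin frame
#'
#' Renders the micro-relief texture described by [texture_params()] on a
#' frame of the given shape, adds Gaussian pixel noise, clips to the 8-bit
#' range and rounds to integer grey levels. Deterministic for a fixed seed.
#'
#' @param shape Integer `(height, width)`. Default `c(256, 300)`, the native
#'   sensor die format.
#' @param params A [texture_params()] object.
#' @return A [capacitive_image()] carrying its `texture_params` as an
#'   attribute (used to refill borders in [shift_and_capture()]).
#' @examples
#' img <- generate_texture(c(64, 64), texture_params(seed = 1))
#' @export
generate_texture <- function(shape = c(256L, 300L), params = texture_params()) {
  stopifnot(inherits(params, "texture_params"))
  h <- as.integer(shape[1]); w <- as.integer(shape[2])
  if (h < 1L || w < 1L) {
    abort("`shape` must have positive height and width.",
          class = "skincap_param_error")
  }
  px <- with_seed(params$seed, render_texture(h, w, params))
  img <- capacitive_image(px)
  attr(img, "texture_params") <- params
  img
}

# line network rendering; RNG state is managed by the caller
render_texture <- function(h, w, params) {
  X <- matrix(rep(0:(w - 1L), each = h), h, w)   # x = column index
  Y <- matrix(rep(0:(h - 1L), times = w), h, w)  # y = row index
  dark <- matrix(0, h, w)
  sigma <- 0.7  # anti-aliasing width of a relief line, px
  for (ang in params$line_angle_set) {
    th <- ang * pi / 180
    u <- X * cos(th) + Y * sin(th)
    v <- X * sin(th) - Y * cos(th)
    phase <- stats::runif(1, 0, params$line_spacing)
    wobble_phase <- stats::runif(1, 0, 2 * pi)
    # gentle sinusoidal wander so lines are not ruler-straight
    u <- u + 1.5 * sin(2 * pi * v / 48 + wobble_phase)
    m <- (u - phase) %% params$line_spacing
    d <- pmin(m, params$line_spacing - m)
    dark <- dark + params$relief_contrast * exp(-d^2 / (2 * sigma^2))
  }
  px <- params$base_level - dark
  if (params$noise_sd > 0) {
    px <- px + stats::rnorm(h * w, sd = params$noise_sd)
  }
  matrix(pmin(255, pmax(0, round(px))), h, w)
}

#' Re-capture an image with translation jitter and fresh noise
#'
#' Emulates replacing the sensor on the same skin site: the scene content is
#' translated by `(dx, dy)` pixels (positive `dx` moves content right,
#' positive `dy` moves it down), the uncovered border is refilled with fresh
#' texture drawn from the image's own texture parameters, and independent
#' Gaussian capture noise is added. This creates the ROI-relocation problem
#' that template matching solves.
#'
#' @param base A [capacitive_image()], ideally one produced by
#'   [generate_texture()] (its texture parameters refill the border; images
#'   without them fall back to their median grey level).
#' @param dx,dy Integer translation in pixels; magnitudes must be smaller
#'   than the image dimensions.
#' @param noise_sd Capture noise SD in grey levels. Default 0.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A [capacitive_image()] of the same size.
#' @export
shift_and_capture <- function(base, dx, dy, noise_sd = 0, seed = NULL) {
  stopifnot(is_capacitive_image(base))
  h <- nrow(base); w <- ncol(base)
  dx <- as.integer(dx); dy <- as.integer(dy)
  if (abs(dx) >= w || abs(dy) >= h) {
    abort("|dx| and |dy| must be smaller than the image dimensions.",
          class = "skincap_param_error")
  }
  tp <- attr(base, "texture_params")
  with_seed(seed, {
    if (!is.null(tp)) {
      fill_params <- tp
      fill_params$seed <- NULL   # draw from the current stream
      fill_params$noise_sd <- 0
      out <- render_texture(h, w, fill_params)
    } else {
      out <- matrix(stats::median(base), h, w)
    }
    src <- as.matrix(base)
    rows_dst <- max(1L, 1L + dy):min(h, h + dy)
    cols_dst <- max(1L, 1L + dx):min(w, w + dx)
    out[rows_dst, cols_dst] <- src[rows_dst - dy, cols_dst - dx]
    if (noise_sd > 0) out <- out + stats::rnorm(h * w, sd = noise_sd)
    img <- capacitive_image(matrix(pmin(255, pmax(0, round(out))), h, w),
                            pixel_pitch = attr(base, "pixel_pitch"))
    attr(img, "texture_params") <- tp
    img
  })
}

# additive brightness shift, clipped to the 8-bit range
shift_brightness <- function(img, delta) {
  px <- pmin(255, pmax(0, round(as.matrix(img) + delta)))
  out <- capacitive_image(matrix(px, nrow(img), ncol(img)),
                          pixel_pitch = attr(img, "pixel_pitch"))
  attr(out, "texture_params") <- attr(img, "texture_params")
  out
}

default_hydration_effect <- list(
  "SPF20"   = c("1h" = 60, "2h" = 50),
  "SPF30"   = c("1h" = 45, "2h" = 38),
  "SPF50+"  = c("1h" = 30, "2h" = 25),
  "control" = c("1h" = 0,  "2h" = 0)
)

default_tewl_effect <- list(
  "SPF20"   = c("1h" = 0.90, "2h" = 0.85),
  "SPF30"   = c("1h" = 0.80, "2h" = 0.72),
  "SPF50+"  = c("1h" = 0.70, "2h" = 0.60),
  "control" = c("1h" = 1.00, "2h" = 1.00)
)

#' Design of a synthetic sunscreen study
#'
#' Describes the four-site volar-forearm design: three sites treated with
#' sunscreens of increasing SPF plus an untreated control, measured before
#' and at later timepoints with capacitive imaging and two TEWL instruments
#' of different repeatability.
#'
#' Default effect sizes encode the qualitative findings the pipeline is
#' meant to recover: hydration (image brightness) rises most for SPF 20 and
#' least for SPF 50+, while TEWL falls most for SPF 50+ and least for
#' SPF 20; the control site does neither. Both effects persist, slightly
#' attenuated (hydration) or deepened (TEWL), at 2 h.
#'
#' @param products Named character vector mapping site ids to product labels;
#'   exactly one site must carry the `"control"` label.
#' @param timepoints Timepoint labels; the first is the pre-application
#'   baseline.
#' @param hydration_effect Named list, product -> named numeric vector of
#'   additive mean-brightness shifts (grey levels) at each post-baseline
#'   timepoint. The control product must be all zero.
#' @param tewl_effect Named list, product -> named numeric vector of
#'   multiplicative TEWL factors at each post-baseline timepoint. The
#'   control product must be all one.
#' @param baseline_tewl Pre-application TEWL in g·m⁻²·h⁻¹. Default 12.
#' @param instrument_cv Named numeric vector, instrument -> coefficient of
#'   variation in percent. Default `c(AquaFlux = 3, VapoMeter = 15)`:
#'   a high-repeatability condenser-chamber device versus an unventilated
#'   chamber device with markedly larger scatter.
#' @param n_replicates Replicate readings per series. Default 5.
#' @param jitter_max Maximum inter-capture translation in pixels. Default 10.
#' @param texture A [texture_params()] for the site base textures.
#' @param capture_noise_sd Per-capture Gaussian pixel noise SD. Default 5.
#' @param seed Integer seed for [generate_study()].
#' @return A `study_design` object (named list).
#' @export
study_design <- function(products = c(site1 = "SPF20", site2 = "SPF30",
                                      site3 = "SPF50+", site4 = "control"),
                         timepoints = c("before", "1h", "2h"),
                         hydration_effect = default_hydration_effect,
                         tewl_effect = default_tewl_effect,
                         baseline_tewl = 12,
                         instrument_cv = c(AquaFlux = 3, VapoMeter = 15),
                         n_replicates = 5L,
                         jitter_max = 10L,
                         texture = texture_params(),
                         capture_noise_sd = 5,
                         seed = 1L) {
  if (sum(products == "control") != 1L) {
    abort("exactly one site must be assigned the 'control' product.",
          class = "skincap_design_error")
  }
  if (length(timepoints) < 2L) {
    abort("need a baseline plus at least one later timepoint.",
          class = "skincap_design_error")
  }
  post <- timepoints[-1]
  for (p in unique(products)) {
    he <- hydration_effect[[p]]; te <- tewl_effect[[p]]
    if (is.null(he) || !all(post %in% names(he)) ||
        is.null(te) || !all(post %in% names(te))) {
      abort(sprintf("effects for product '%s' must cover timepoints: %s",
                    p, paste(post, collapse = ", ")),
            class = "skincap_design_error")
    }
  }
  if (any(hydration_effect[["control"]][post] != 0) ||
      any(tewl_effect[["control"]][post] != 1)) {
    abort("control must have zero hydration effect and unit TEWL effect.",
          class = "skincap_design_error")
  }
  if (any(instrument_cv < 0) || is.null(names(instrument_cv))) {
    abort("`instrument_cv` must be a named vector of non-negative percentages.",
          class = "skincap_design_error")
  }
  if (n_replicates < 1L) {
    abort("`n_replicates` must be at least 1.", class = "skincap_design_error")
  }
  if (baseline_tewl <= 0) {
    abort("`baseline_tewl` must be positive.", class = "skincap_design_error")
  }
  structure(list(products = products, timepoints = timepoints,
                 hydration_effect = hydration_effect,
                 tewl_effect = tewl_effect,
                 baseline_tewl = baseline_tewl,
                 instrument_cv = instrument_cv,
                 n_replicates = as.integer(n_replicates),
                 jitter_max = as.integer(jitter_max),
                 texture = texture,
                 capture_noise_sd = capture_noise_sd,
                 seed = as.integer(seed)),
            class = "study_design")
}

# effect of `product` at `timepoint` (baseline: additive 0 / multiplicative 1)
effect_at <- function(effect_list, product, timepoint, baseline, identity_value) {
  if (timepoint == baseline) return(identity_value)
  unname(effect_list[[product]][[timepoint]])
}

#' Simulate replicate TEWL readings
#'
#' Draws `n` readings from a normal law with the given mean and a standard
#' deviation of `mean * cv / 100`, redrawing any non-positive values (the
#' instrument reports positive flux only).
#'
#' @param mean_value True mean TEWL (g·m⁻²·h⁻¹), positive.
#' @param cv True coefficient of variation in percent.
#' @param n Number of replicates.
#' @return Numeric vector of length `n`.
#' @export
simulate_tewl <- function(mean_value, cv, n) {
  stopifnot(mean_value > 0, cv >= 0, n >= 1)
  vals <- stats::rnorm(n, mean = mean_value, sd = mean_value * cv / 100)
  while (any(vals <= 0)) {
    bad <- vals <= 0
    vals[bad] <- stats::rnorm(sum(bad), mean = mean_value,
                              sd = mean_value * cv / 100)
  }
  vals
}

#' Generate a full synthetic study
#'
#' Produces, for every site and timepoint, a capacitive frame (the site's
#' own micro-relief texture, brightened by the product's hydration effect,
#' re-captured with translation jitter and fresh noise at post-baseline
#' timepoints) and, for every site, timepoint and instrument, a series of
#' replicate TEWL readings with the instrument's CV. All ground truth
#' (true translations, true means, true brightness shifts) is recorded.
#'
#' All randomness derives from `design$seed`: a single RNG stream is seeded
#' once and consumed in a fixed site-major, timepoint-minor order, so any
#' two runs of the same design are identical.
#'
#' @param design A [study_design()].
#' @param shape Frame shape `(height, width)`. Default `c(256, 300)`.
#' @return A `synthetic_study` object: list with `images` (tibble: site_id,
#'   product, timepoint, image list-column, true_dx, true_dy,
#'   true_brightness_shift), `measurements` (long tibble in the
#'   [read_measurements()] schema), `truth` (tibble of true TEWL means), and
#'   the `design` and `shape` used.
#' @export
generate_study <- function(design, shape = c(256L, 300L)) {
  stopifnot(inherits(design, "study_design"))
  baseline <- design$timepoints[1]
  sites <- names(design$products)

  with_seed(design$seed, {
    img_rows <- list(); meas_rows <- list(); truth_rows <- list()
    for (s in sites) {
      product <- design$products[[s]]
      tp <- design$texture
      tp$seed <- NULL
      tp$noise_sd <- 0
      base <- generate_texture(shape, tp)  # draws from the seeded stream
      for (t in design$timepoints) {
        h_eff <- effect_at(design$hydration_effect, product, t, baseline, 0)
        if (t == baseline) {
          dx <- 0L; dy <- 0L
        } else {
          dx <- sample(-design$jitter_max:design$jitter_max, 1L)
          dy <- sample(-design$jitter_max:design$jitter_max, 1L)
        }
        frame <- shift_and_capture(shift_brightness(base, h_eff), dx, dy,
                                   noise_sd = design$capture_noise_sd)
        img_rows[[length(img_rows) + 1L]] <- tibble::tibble(
          site_id = s, product = product, timepoint = t,
          image = list(frame), true_dx = dx, true_dy = dy,
          true_brightness_shift = h_eff)
        t_eff <- effect_at(design$tewl_effect, product, t, baseline, 1)
        true_mean <- design$baseline_tewl * t_eff
        for (ins in names(design$instrument_cv)) {
          vals <- simulate_tewl(true_mean, design$instrument_cv[[ins]],
                                design$n_replicates)
          meas_rows[[length(meas_rows) + 1L]] <- tibble::tibble(
            site_id = s, timepoint = t, instrument = ins,
            replicate = seq_along(vals), value = vals)
          truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
            site_id = s, product = product, timepoint = t, instrument = ins,
            true_tewl_mean = true_mean, true_cv = design$instrument_cv[[ins]])
        }
      }
    }
    structure(list(images = dplyr::bind_rows(img_rows),
                   measurements = dplyr::bind_rows(meas_rows),
                   truth = dplyr::bind_rows(truth_rows),
                   design = design, shape = as.integer(shape)),
              class = "synthetic_study")
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d frames (%d x %d px), %d measurement rows\n",
              nrow(x$images), x$shape[1], x$shape[2], nrow(x$measurements)))
  cat(sprintf("  sites: %s\n",
              paste(sprintf("%s=%s", names(x$design$products),
                            x$design$products), collapse = ", ")))
  cat(sprintf("  timepoints: %s; instruments: %s\n",
              paste(x$design$timepoints, collapse = ", "),
              paste(names(x$design$instrument_cv), collapse = ", ")))
  invisible(x)
}
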