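#' Analyse a synthetic study end to end
#'
#' Runs the full analysis sequence on a generated study: relocate the ROI
#' from each site's baseline frame in the later frames by template matching,
#' compute permittivity statistics over the relocated ROI, summarise the
#' TEWL series with before/after deltas, form per-site hydration/TEWL
#' ratios, and rank all frames by PCA distance to the control site's final
#' frame.
#'
#' @param study A [generate_study()] result.
#' @param roi A [roi_rect()] selected on the baseline frames. Default a
#'   64 x 64 window away from the borders so every jittered capture still
#'   contains it.
#' @param method,literal Template-matching options; default `CCorr_Normed`.
#' @param cal A [calibration()] for the hydration statistics.
#' @param n_bins Histogram bins for [roi_stats()]. Default 32.
#' @param instrument Instrument used for the hydration/TEWL ratio; default
#'   the design's first (lowest-CV instruments should be listed first).
#' @param n_components PCA components; default `min(8, rank)`.
#' @param rooted Use the rooted PCA distance. Default `FALSE`.
#' @return A `study_analysis`: list of tibbles `relocation`, `hydration`,
#'   `tewl`, `ratios`, `pca` plus the fitted `pca_model` and the inputs.
#' @export
analyze_study <- function(study, roi = roi_rect(120, 96, 64, 64),
                          method = "CCorr_Normed", literal = FALSE,
                          cal = calibration(), n_bins = 32L,
                          instrument = NULL, n_components = NULL,
                          rooted = FALSE) {
  stopifnot(inherits(study, "synthetic_study"))
  baseline <- study$design$timepoints[1]
  if (is.null(instrument)) instrument <- names(study$design$instrument_cv)[1]

  # --- ROI relocation: baseline frame is the reference for its own site
  reloc <- study$images |>
    dplyr::group_by(.data$site_id) |>
    dplyr::group_modify(function(df, key) {
      ref <- df$image[df$timepoint == baseline][[1]]
      out <- relocate_roi(ref, roi,
                          setNames(df$image, df$timepoint),
                          method = method, literal = literal)
      out$timepoint <- df$timepoint
      out$true_dx <- df$true_dx
      out$true_dy <- df$true_dy
      dplyr::select(out, -"target")
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(exact = .data$x == roi$x + .data$true_dx &
                          .data$y == roi$y + .data$true_dy)

  # --- permittivity statistics over each frame's relocated ROI
  hydration <- study$images |>
    dplyr::left_join(reloc[c("site_id", "timepoint", "x", "y", "w", "h")],
                     by = c("site_id", "timepoint")) |>
    dplyr::rowwise() |>
    dplyr::mutate(stats = list(roi_stats(.data$image,
                                         roi_rect(.data$x, .data$y,
                                                  .data$w, .data$h),
                                         cal = cal, n_bins = n_bins))) |>
    dplyr::ungroup() |>
    dplyr::transmute(.data$site_id, .data$product, .data$timepoint,
                     mean = purrr::map_dbl(.data$stats, "mean"),
                     sd = purrr::map_dbl(.data$stats, "sd")) |>
    hydration_change(baseline = baseline)

  # --- TEWL report
  tewl <- site_report(study$measurements, baseline = baseline) |>
    dplyr::left_join(dplyr::distinct(study$images, .data$site_id, .data$product),
                     by = "site_id")

  # --- hydration / TEWL ratio per site and timepoint
  ratios <- hydration |>
    dplyr::inner_join(
      dplyr::filter(tewl, .data$instrument == !!instrument) |>
        dplyr::select("site_id", "timepoint", tewl_mean = "mean"),
      by = c("site_id", "timepoint")) |>
    dplyr::mutate(ratio = hydration_tewl_ratio(.data$mean, .data$tewl_mean)) |>
    dplyr::select("site_id", "product", "timepoint", eps_mean = "mean",
                  "tewl_mean", "ratio")

  # --- PCA ranking against the control site's final frame
  final_tp <- study$design$timepoints[length(study$design$timepoints)]
  control_site <- names(study$design$products)[study$design$products == "control"]
  labels <- sprintf("%s@%s", study$images$product, study$images$timepoint)
  all_imgs <- setNames(study$images$image, labels)
  ref_label <- sprintf("control@%s", final_tp)
  model <- fit_pca(unname(all_imgs), n_components = n_components)
  pca <- rank_sites(all_imgs[[ref_label]], all_imgs, model = model,
                    rooted = rooted) |>
    dplyr::left_join(
      tibble::tibble(label = labels,
                     site_id = study$images$site_id,
                     product = study$images$product,
                     timepoint = study$images$timepoint),
      by = "label")

  structure(list(relocation = reloc, hydration = hydration, tewl = tewl,
                 ratios = ratios, pca = pca, pca_model = model,
                 roi = roi, method = method, instrument = instrument,
                 baseline = baseline, final_tp = final_tp,
                 control_site = control_site,
                 design = study$design),
            class = "study_analysis")
}

#' @export
print.study_analysis <- function(x, ...) {
  cat(sprintf("<study_analysis> method %s, ROI %s, instrument %s\n",
              x$method, format(x$roi), x$instrument))
  ck <- ordering_checks(x)
  for (i in seq_len(nrow(ck))) {
    cat(sprintf("  %-22s %s\n", ck$check[i], if (ck$pass[i]) "PASS" else "fail"))
  }
  invisible(x)
}

#' Qualitative ordering checks on an analysed study
#'
#' The three headline orderings the analysis is designed to recover:
#'
#' * `tewl_ordering` — at the final timepoint all treated sites show a TEWL
#'   decrease, with the magnitude increasing with SPF
#'   (|SPF 50+| > |SPF 30| > |SPF 20|) and the control's change smallest in
#'   magnitude;
#' * `hydration_ordering` — at every post-baseline timepoint the treated
#'   sites' permittivity deltas are positive and decrease with SPF
#'   (SPF 20 > SPF 30 > SPF 50+);
#' * `pca_ordering` — the control site's earlier frames and all
#'   pre-application frames lie nearer (in PCA distance) to the control
#'   site's final frame than any treated post-application frame.
#'
#' @param analysis A [analyze_study()] result.
#' @param instrument Instrument whose TEWL deltas are checked; default the
#'   analysis' ratio instrument.
#' @return Tibble with columns `check` and `pass`.
#' @export
ordering_checks <- function(analysis, instrument = NULL) {
  stopifnot(inherits(analysis, "study_analysis"))
  if (is.null(instrument)) instrument <- analysis$instrument
  spf <- c("SPF20", "SPF30", "SPF50+")

  tw <- analysis$tewl |>
    dplyr::filter(.data$instrument == !!instrument,
                  .data$timepoint == analysis$final_tp)
  d <- setNames(tw$delta, tw$product)
  tewl_ok <- !anyNA(d[spf]) && all(d[spf] < 0) &&
    abs(d[["SPF50+"]]) > abs(d[["SPF30"]]) &&
    abs(d[["SPF30"]]) > abs(d[["SPF20"]]) &&
    abs(d[["control"]]) < min(abs(d[spf]))

  post <- setdiff(unique(analysis$hydration$timepoint), analysis$baseline)
  hyd_ok <- all(vapply(post, function(t) {
    h <- analysis$hydration |> dplyr::filter(.data$timepoint == t)
    hd <- setNames(h$delta, h$product)
    all(hd[spf] > 0) && hd[["SPF20"]] > hd[["SPF30"]] &&
      hd[["SPF30"]] > hd[["SPF50+"]]
  }, logical(1)))

  pc <- analysis$pca
  near <- pc$d[pc$product == "control" | pc$timepoint == analysis$baseline]
  far <- pc$d[pc$product != "control" & pc$timepoint != analysis$baseline]
  pca_ok <- length(near) > 0 && length(far) > 0 && max(near) < min(far)

  tibble::tibble(check = c("tewl_ordering", "hydration_ordering",
                           "pca_ordering"),
                 pass = c(tewl_ok, hyd_ok, pca_ok))
}

# ---- config-driven pipeline ------------------------------------------------

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      abort(sprintf("config file not found: %s", config),
            class = "skincap_io_error")
    }
    ext <- tolower(tools::file_ext(config))
    config <- switch(ext,
      yaml = , yml = yaml::read_yaml(config),
      json = jsonlite::read_json(config, simplifyVector = TRUE),
      abort(sprintf("config must be YAML or JSON, got '.%s'.", ext),
            class = "skincap_schema_error"))
  }
  if (!is.list(config)) {
    abort("config must be a file path or a named list.",
          class = "skincap_schema_error")
  }
  config
}

config_field <- function(config, name, default) {
  if (is.null(config[[name]])) default else config[[name]]
}

# nested map (product -> timepoint -> value) to the named-vector-list form
as_effect_list <- function(x) lapply(x, function(v) unlist(v))

design_from_config <- function(config) {
  args <- list()
  if (!is.null(config$products)) args$products <- unlist(config$products)
  for (f in c("timepoints", "baseline_tewl", "n_replicates", "jitter_max",
              "capture_noise_sd", "seed")) {
    if (!is.null(config[[f]])) args[[f]] <- config[[f]]
  }
  if (!is.null(config$instrument_cv)) {
    args$instrument_cv <- unlist(config$instrument_cv)
  }
  if (!is.null(config$hydration_effect)) {
    args$hydration_effect <- as_effect_list(config$hydration_effect)
  }
  if (!is.null(config$tewl_effect)) {
    args$tewl_effect <- as_effect_list(config$tewl_effect)
  }
  if (!is.null(config$texture)) {
    args$texture <- do.call(texture_params, config$texture)
  }
  tryCatch(do.call(study_design, args),
           error = function(e) {
             abort(sprintf("invalid study design in config: %s",
                           conditionMessage(e)),
                   class = "skincap_schema_error")
           })
}

#' Run the full pipeline from a config
#'
#' Generates (or re-generates, deterministically) the synthetic study
#' described by the config, analyses it with [analyze_study()], evaluates
#' the [ordering_checks()], and writes a report bundle: CSV tables for
#' measurements, TEWL report, hydration deltas, ROI relocation, ratios and
#' PCA distances, a `summary.json`, and a timestamped stage log (to file
#' and, with `quiet = FALSE`, to the console).
#'
#' Config fields (all optional except `seed`): `seed`, `shape`, study-design
#' overrides (`products`, `timepoints`, `hydration_effect`, `tewl_effect`,
#' `baseline_tewl`, `instrument_cv`, `n_replicates`, `jitter_max`,
#' `capture_noise_sd`, `texture`), `roi` (list x, y, w, h), `method`,
#' `literal`, `calibration` (grey_low, grey_high, eps_low, eps_high),
#' `n_bins`, `instrument`, `n_components`, `rooted`.
#'
#' @param config Path to a YAML/JSON config file, or an equivalent named
#'   list.
#' @param out_dir Output directory (created if needed); `NULL` analyses
#'   without writing files.
#' @param quiet Suppress console log messages. Default `FALSE`.
#' @return Invisibly, a list with `study`, `analysis`, `checks`, `summary`
#'   (the summary written to JSON) and `files` (paths written).
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  config <- read_config(config)
  if (is.null(config$seed)) {
    abort("config is missing required field `seed`.",
          class = "skincap_schema_error")
  }
  log_lines <- character()
  say <- function(stage, msg) {
    line <- sprintf("[%s] [%s] %s",
                    format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, msg)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }

  say("config", sprintf("seed %d", config$seed))
  design <- design_from_config(config)
  shape <- as.integer(config_field(config, "shape", c(256L, 300L)))

  say("simulate", sprintf("generating study (%d x %d frames)",
                          shape[1], shape[2]))
  study <- generate_study(design, shape = shape)

  roi_cfg <- config_field(config, "roi", list(x = 120, y = 96, w = 64, h = 64))
  cal_cfg <- config_field(config, "calibration", NULL)
  cal <- if (is.null(cal_cfg)) calibration() else do.call(calibration, cal_cfg)

  say("analyze", "relocating ROI, computing hydration, TEWL, PCA")
  analysis <- analyze_study(
    study,
    roi = do.call(roi_rect, roi_cfg),
    method = config_field(config, "method", "CCorr_Normed"),
    literal = isTRUE(config$literal),
    cal = cal,
    n_bins = config_field(config, "n_bins", 32L),
    instrument = config_field(config, "instrument", NULL),
    n_components = config_field(config, "n_components", NULL),
    rooted = isTRUE(config$rooted))

  checks <- ordering_checks(analysis)
  no_sep <- all(vapply(
    design$hydration_effect[names(design$hydration_effect) != "control"],
    function(v) all(v == 0), logical(1)))
  say("checks", if (no_sep) "zero-effect design: no separation expected"
      else paste(sprintf("%s=%s", checks$check, checks$pass), collapse = " "))

  summary <- list(
    seed = config$seed,
    shape = shape,
    no_separation_design = no_sep,
    tewl_delta = analysis$tewl |>
      dplyr::filter(.data$instrument == analysis$instrument,
                    .data$timepoint != analysis$baseline) |>
      dplyr::select("site_id", "product", "timepoint", "delta", "delta_pct"),
    hydration_delta = analysis$hydration |>
      dplyr::filter(.data$timepoint != analysis$baseline) |>
      dplyr::select("site_id", "product", "timepoint", "delta"),
    ratio = analysis$ratios |>
      dplyr::select("site_id", "product", "timepoint", "ratio"),
    pca_ranking = analysis$pca |> dplyr::select("label", "d"),
    checks = checks)

  files <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(df, name) {
      p <- file.path(out_dir, name)
      readr::write_csv(df, p)
      files <<- c(files, p)
      say("write", name)
    }
    w(study$measurements, "measurements.csv")
    w(analysis$tewl, "tewl_report.csv")
    w(analysis$hydration, "hydration.csv")
    w(analysis$relocation |> dplyr::select(-dplyr::any_of("image")),
      "relocation.csv")
    w(analysis$ratios, "ratios.csv")
    w(analysis$pca, "pca_distances.csv")
    sj <- file.path(out_dir, "summary.json")
    jsonlite::write_json(summary, sj, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    files <- c(files, sj)
    say("write", "summary.json")
    lg <- file.path(out_dir, "pipeline.log")
    writeLines(log_lines, lg)
    files <- c(files, lg)
  }
  invisible(list(study = study, analysis = analysis, checks = checks,
                 summary = summary, files = files))
}
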