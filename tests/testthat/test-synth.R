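test_that("texture generation is deterministic and respects its parameters", {
  flat <- generate_texture(c(20, 30), texture_params(base_level = 120,
                                                     relief_contrast = 0,
                                                     noise_sd = 0, seed = 1))
  expect_true(all(as.matrix(flat) == 120L))
  expect_identical(dim(flat), c(20L, 30L))

  a <- generate_texture(c(40, 40), texture_params(seed = 42, noise_sd = 5))
  b <- generate_texture(c(40, 40), texture_params(seed = 42, noise_sd = 5))
  expect_identical(as.matrix(a), as.matrix(b))
  c <- generate_texture(c(40, 40), texture_params(seed = 43, noise_sd = 5))
  expect_false(identical(as.matrix(a), as.matrix(c)))

  lo <- generate_texture(c(64, 64), texture_params(base_level = 100,
                                                   noise_sd = 5, seed = 7))
  hi <- generate_texture(c(64, 64), texture_params(base_level = 160,
                                                   noise_sd = 5, seed = 7))
  expect_lt(abs((mean(hi) - mean(lo)) - 60), 1)

  expect_error(generate_texture(c(0, 10)), class = "skincap_param_error")
  expect_error(texture_params(line_spacing = 1), class = "skincap_param_error")
})

test_that("shift_and_capture translates content and refills the border", {
  base <- generate_texture(c(50, 60), texture_params(seed = 5))
  same <- shift_and_capture(base, 0, 0, noise_sd = 0)
  expect_identical(as.matrix(same), as.matrix(base))

  dx <- 7L; dy <- 3L
  sh <- shift_and_capture(base, dx, dy, noise_sd = 0, seed = 9)
  # interior: content at (x, y) in base appears at (x+dx, y+dy)
  expect_identical(as.matrix(sh)[(1 + dy):50, (1 + dx):60],
                   as.matrix(base)[1:(50 - dy), 1:(60 - dx)])
  # reproducible under the same seed
  sh2 <- shift_and_capture(base, dx, dy, noise_sd = 0, seed = 9)
  expect_identical(as.matrix(sh), as.matrix(sh2))

  neg <- shift_and_capture(base, -4, -6, noise_sd = 0)
  expect_identical(as.matrix(neg)[1:(50 - 6), 1:(60 - 4)],
                   as.matrix(base)[7:50, 5:60])

  expect_error(shift_and_capture(base, 60, 0), class = "skincap_param_error")
})

test_that("generated studies carry the designed effects in their ground truth", {
  # zero effects, zero CV: every TEWL replicate equals the baseline exactly
  null_design <- study_design(
    hydration_effect = list("SPF20" = c("1h" = 0), "SPF30" = c("1h" = 0),
                            "SPF50+" = c("1h" = 0), "control" = c("1h" = 0)),
    tewl_effect = list("SPF20" = c("1h" = 1), "SPF30" = c("1h" = 1),
                       "SPF50+" = c("1h" = 1), "control" = c("1h" = 1)),
    timepoints = c("before", "1h"),
    instrument_cv = c(A = 0), capture_noise_sd = 0, seed = 3)
  null_study <- generate_study(null_design, shape = c(40, 40))
  expect_true(all(null_study$measurements$value == null_design$baseline_tewl))

  # default sunscreen design: raw frame means at 1 h ordered by hydration effect
  st <- generate_study(study_design(seed = 1), shape = c(96, 96))
  at_1h <- st$images[st$images$timepoint == "1h", ]
  m <- vapply(at_1h$image, mean, numeric(1))
  names(m) <- at_1h$product
  expect_true(m[["SPF20"]] > m[["SPF30"]])
  expect_true(m[["SPF30"]] > m[["SPF50+"]])
  expect_true(m[["SPF50+"]] > m[["control"]])

  # determinism of the whole study
  st2 <- generate_study(study_design(seed = 1), shape = c(96, 96))
  expect_identical(st$measurements, st2$measurements)
  expect_identical(as.matrix(st$images$image[[5]]),
                   as.matrix(st2$images$image[[5]]))
})

test_that("frame mean-brightness shifts recover the designed hydration effect", {
  # jitter-free captures: the whole-frame mean shift estimates the effect
  # with SE sqrt(2) * noise_sd / sqrt(pixels) (two independent noise fields)
  st <- generate_study(study_design(seed = 8, jitter_max = 0),
                       shape = c(128, 128))
  tol <- 3 * sqrt(2) * st$design$capture_noise_sd / 128
  df <- st$images
  for (s in unique(df$site_id)) {
    before <- df$image[df$site_id == s & df$timepoint == "before"][[1]]
    for (t in c("1h", "2h")) {
      row <- df[df$site_id == s & df$timepoint == t, ]
      shift <- mean(row$image[[1]]) - mean(before)
      expect_lt(abs(shift - row$true_brightness_shift), tol)
    }
  }
  # with jitter, the relocated ROI (not the whole frame) carries the effect:
  # borders are refilled with unbrightened fresh texture, diluting frame means
  jit <- generate_study(study_design(seed = 8, jitter_max = 10),
                        shape = c(128, 128))
  an_roi <- roi_rect(48, 48, 32, 32)
  reloc <- relocate_roi(jit$images$image[[1]], an_roi,
                        list(jit$images$image[[2]]))
  stats_before <- roi_stats(jit$images$image[[1]], an_roi,
                            calibration(0, 255, 0, 255))
  stats_after <- roi_stats(jit$images$image[[2]],
                           roi_rect(reloc$x, reloc$y, reloc$w, reloc$h),
                           calibration(0, 255, 0, 255))
  expect_lt(abs((stats_after$mean - stats_before$mean) -
                  jit$images$true_brightness_shift[2]),
            3 * sqrt(2) * jit$design$capture_noise_sd / 32 + 0.5)
})

test_that("study designs are validated", {
  expect_error(study_design(products = c(a = "SPF20", b = "SPF30")),
               class = "skincap_design_error")
  expect_error(study_design(baseline_tewl = -1), class = "skincap_design_error")
  expect_error(study_design(n_replicates = 0), class = "skincap_design_error")
  expect_error(study_design(instrument_cv = c(A = -3)),
               class = "skincap_design_error")
  # control with a non-zero hydration effect is not a valid design
  he <- list("SPF20" = c("1h" = 60, "2h" = 50), "SPF30" = c("1h" = 45, "2h" = 38),
             "SPF50+" = c("1h" = 30, "2h" = 25), "control" = c("1h" = 5, "2h" = 0))
  expect_error(study_design(hydration_effect = he),
               class = "skincap_design_error")
})
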