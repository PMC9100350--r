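test_that("surfaces have valid-placement dimensions and trivial exact matches", {
  img <- random_test_image(6, 7)
  tpl <- crop_image(img, roi_rect(2, 1, 3, 4))
  s <- match_surface(img, tpl, "SqDiff")
  expect_identical(dim(s$scores), c(6L - 4L + 1L, 7L - 3L + 1L))

  # template == image: 1x1 surface, SqDiff exactly 0
  whole <- match_surface(img, img, "SqDiff")
  expect_identical(dim(whole$scores), c(1L, 1L))
  expect_identical(whole$scores[1, 1], 0)

  # planted template: SqDiff minimum of 0 exactly at the crop position
  frame <- generate_texture(c(40, 40), texture_params(seed = 2))
  tpl2 <- crop_image(frame, roi_rect(11, 6, 9, 9))
  bm <- best_match(match_surface(frame, tpl2, "SqDiff"))
  expect_identical(bm$location, c(x = 11L, y = 6L))
  expect_identical(bm$score, 0)

  expect_error(match_surface(tpl, img, "SqDiff"), class = "skincap_size_error")
})

test_that("all six methods, both modes, equal the nested-loop oracle", {
  set.seed(301)
  for (trial in 1:20) {
    H <- sample(4:8, 1); W <- sample(4:8, 1)
    h <- sample(2:3, 1); w <- sample(2:3, 1)
    I <- random_test_image(H, W)
    T <- random_test_image(h, w)
    for (m in all_tm_methods) {
      for (lit in c(FALSE, TRUE)) {
        got <- match_surface(I, T, m, literal = lit)$scores
        want <- oracle_surface(as.matrix(I), as.matrix(T), m, literal = lit)
        expect_equal(got, want, tolerance = 1e-9,
                     label = sprintf("%s literal=%s trial=%d", m, lit, trial))
      }
    }
  }
})

test_that("best_match follows the min/max rule and breaks ties by y then x", {
  mk <- function(scores, method) {
    structure(list(scores = scores, method = method, literal = FALSE,
                   template_dim = c(1L, 1L)), class = "match_surface")
  }
  expect_identical(best_match(mk(matrix(c(0, 5, 5, 5), 2, 2), "SqDiff"))$location,
                   c(x = 0L, y = 0L))
  # all-tie surface: smallest y, then smallest x
  expect_identical(best_match(mk(matrix(1, 2, 2), "CCorr"))$location,
                   c(x = 0L, y = 0L))
  # tie between (x=1, y=0) and (x=0, y=1): y wins
  sc <- matrix(c(0, 7, 7, 3), 2, 2)  # [y=0,x=0]=0 [y=1,x=0]=7 [y=0,x=1]=7
  expect_identical(best_match(mk(sc, "CCoeff"))$location, c(x = 1L, y = 0L))
  expect_error(best_match(mk(matrix(numeric(0), 0, 0), "SqDiff")),
               class = "skincap_size_error")
})

test_that("normalised scores are bounded and SqDiff vanishes only on equality", {
  set.seed(302)
  for (trial in 1:20) {
    I <- random_test_image(8, 8)
    T <- random_test_image(3, 3)
    ccn <- match_surface(I, T, "CCoeff_Normed")$scores
    expect_true(all(ccn >= -1 - 1e-9 & ccn <= 1 + 1e-9))
    crn <- match_surface(I, T, "CCorr_Normed")$scores
    expect_true(all(crn >= 0 - 1e-9 & crn <= 1 + 1e-9))
    sq <- match_surface(I, T, "SqDiff")$scores
    # zero iff the window equals the template
    for (idx in which(sq == 0)) {
      y <- (idx - 1) %% nrow(sq); x <- (idx - 1) %/% nrow(sq)
      win <- as.matrix(I)[(y + 1):(y + 3), (x + 1):(x + 3)]
      expect_identical(win, as.matrix(T))
    }
  }
})

test_that("CCoeff-family scores are invariant to a common brightness offset", {
  set.seed(303)
  I <- matrix(sample(0:200, 64, replace = TRUE), 8, 8)
  T <- matrix(sample(0:200, 9, replace = TRUE), 3, 3)
  for (m in c("CCoeff", "CCoeff_Normed")) {
    base <- match_surface(I, T, m)$scores
    shifted <- match_surface(I + 40, T + 40, m)$scores
    expect_equal(base, shifted, tolerance = 1e-9)
  }
})

test_that("degenerate templates raise errors; featureless windows score worst", {
  img <- random_test_image(6, 6)
  zero_tpl <- matrix(0, 2, 2)
  expect_error(match_surface(img, zero_tpl, "SqDiff_Normed"),
               class = "skincap_degenerate_error")
  expect_error(match_surface(img, zero_tpl, "CCorr_Normed"),
               class = "skincap_degenerate_error")
  expect_error(match_surface(img, matrix(7, 2, 2), "CCoeff_Normed"),
               class = "skincap_degenerate_error")
  # plain methods tolerate constant templates
  expect_silent(match_surface(img, matrix(7, 2, 2), "CCoeff"))

  # constant window under CCoeff_Normed scores 0 (excluded from the max)
  flat <- matrix(50, 4, 4); flat[1, 1] <- 60  # mostly constant image
  tpl <- matrix(c(1, 2, 3, 4), 2, 2)
  s <- match_surface(flat, tpl, "CCoeff_Normed")$scores
  expect_true(all(is.finite(s)))
  expect_identical(s[3, 3], 0)  # fully-constant window
})

test_that("ROI relocation recovers known translations", {
  ref <- generate_texture(c(80, 80), texture_params(seed = 12))
  roi <- roi_rect(24, 30, 32, 32)

  # target identical to reference: the ROI comes back unchanged
  same <- relocate_roi(ref, roi, list(ref))
  expect_identical(c(same$x, same$y), c(roi$x, roi$y))

  # noiseless known shifts are recovered exactly, ground truth from generation
  set.seed(304)
  for (trial in 1:5) {
    dx <- sample(-8:8, 1); dy <- sample(-8:8, 1)
    tgt <- shift_and_capture(ref, dx, dy, noise_sd = 0)
    r <- relocate_roi(ref, roi, list(tgt))
    expect_identical(c(r$x, r$y), c(roi$x + dx, roi$y + dy))
  }

  # a short jittered sequence: one rect per frame, each inside its frame
  frames <- lapply(1:3, function(i) shift_and_capture(ref, i, -i, noise_sd = 3,
                                                      seed = 400 + i))
  rr <- relocate_roi(ref, roi, frames)
  expect_equal(nrow(rr), 3L)
  expect_true(all(rr$x >= 0 & rr$x + rr$w <= 80))
  expect_true(all(rr$y >= 0 & rr$y + rr$h <= 80))
})
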