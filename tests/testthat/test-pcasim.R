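test_that("fitted components match a dense covariance eigendecomposition", {
  imgs <- tiny_images(6, seed = 41)
  model <- fit_pca(imgs, n_components = 4)
  oracle <- oracle_pca_components(imgs, 4)
  expect_equal(model$var_explained, oracle$values, tolerance = 1e-8)
  for (i in 1:4) {
    got <- model$components[i, ]
    want <- oracle$vectors[, i]
    # eigenvectors agree up to sign
    expect_lt(min(sum((got - want)^2), sum((got + want)^2)), 1e-16 * 9 + 1e-12)
  }
  # orthonormality
  G <- model$components %*% t(model$components)
  expect_equal(G, diag(4), tolerance = 1e-8)
  # explained variances non-increasing
  expect_true(all(diff(model$var_explained) <= 1e-12))
  # sign convention: largest-magnitude coordinate positive
  for (i in 1:4) {
    expect_gt(model$components[i, which.max(abs(model$components[i, ]))], 0)
  }
})

test_that("two-image PCA gives a component parallel to the difference", {
  a <- capacitive_image(matrix(c(10L, 20L, 30L, 40L), 2, 2))
  b <- capacitive_image(matrix(c(50L, 10L, 35L, 60L), 2, 2))
  model <- fit_pca(list(a, b), n_components = 1)
  d <- as.vector(t(as.matrix(a))) - as.vector(t(as.matrix(b)))
  d <- d / sqrt(sum(d^2))
  cosang <- abs(sum(model$components[1, ] * d))
  expect_equal(cosang, 1, tolerance = 1e-10)
})

test_that("projection is exact at full rank and zero at the mean", {
  imgs <- tiny_images(5, seed = 42)
  model <- fit_pca(imgs, n_components = 4)  # full rank for 5 images

  # projecting the collection mean gives all-zero scores
  mean_img <- matrix(model$mean, 3, 3, byrow = TRUE)
  expect_equal(project(model, mean_img)$scores, rep(0, 4), tolerance = 1e-9)

  # training images reconstruct exactly at full rank
  for (img in imgs) {
    rec <- reconstruct(project(model, img))
    expect_equal(rec, {
      m <- as.matrix(img); storage.mode(m) <- "double"; m
    }, tolerance = 1e-6)
  }

  expect_error(project(model, random_test_image(4, 4)),
               class = "skincap_size_error")
  expect_error(fit_pca(list(imgs[[1]], random_test_image(4, 4))),
               class = "skincap_size_error")
  expect_error(fit_pca(imgs, n_components = 10), class = "skincap_param_error")
})

test_that("pca_distance equals the brute-force double sum", {
  set.seed(43)
  for (trial in 1:20) {
    n <- sample(1:4, 1); p <- sample(1:9, 1)
    m1 <- matrix(rnorm(n * p), n, p)
    m2 <- matrix(rnorm(n * p), n, p)
    expect_equal(pca_distance(m1, m2), oracle_pca_distance(m1, m2),
                 tolerance = 1e-9)
    expect_equal(pca_distance(m1, m2, rooted = TRUE),
                 oracle_pca_distance(m1, m2, rooted = TRUE), tolerance = 1e-9)
    # d(a, a) = 0; symmetry; rooted/literal algebraic relation
    expect_identical(pca_distance(m1, m1), 0)
    expect_equal(pca_distance(m1, m2), pca_distance(m2, m1))
    expect_equal(pca_distance(m1, m2),
                 (pca_distance(m1, m2, rooted = TRUE) * n)^2 / n)
  }
  # single-coordinate closed form: (3 - 1)^2 / 1 = 4
  expect_equal(pca_distance(matrix(3), matrix(1)), 4)
  expect_error(pca_distance(matrix(1, 2, 2), matrix(1, 2, 3)),
               class = "skincap_size_error")
})

test_that("projection-based distances agree with materialised matrices", {
  imgs <- tiny_images(6, seed = 44)
  model <- fit_pca(imgs, n_components = 3)
  p1 <- project(model, imgs[[1]]); p2 <- project(model, imgs[[2]])
  expect_equal(pca_distance(p1, p2),
               oracle_pca_distance(as.matrix(p1), as.matrix(p2)),
               tolerance = 1e-9)
  expect_identical(pca_distance(p1, p1), 0)

  # Parseval at full rank: the double sum equals the squared centred distance
  full <- fit_pca(imgs, n_components = 5)
  q1 <- project(full, imgs[[1]]); q2 <- project(full, imgs[[2]])
  v1 <- as.vector(t(as.matrix(imgs[[1]])))
  v2 <- as.vector(t(as.matrix(imgs[[2]])))
  expect_equal(pca_distance(q1, q2) * full$n_components,
               sum((v1 - v2)^2), tolerance = 1e-6)
})

test_that("rank_sites orders candidates by distance with stable ties", {
  imgs <- tiny_images(6, seed = 45)
  names(imgs) <- paste0("img", 1:6)
  model <- fit_pca(unname(imgs), n_components = 4)

  solo <- rank_sites(imgs[[1]], imgs[1], model = model)
  expect_equal(solo$label, "img1")
  expect_equal(solo$d, 0)

  r <- rank_sites(imgs[[3]], imgs, model = model)
  expect_equal(r$label[1], "img3")
  expect_equal(r$d[1], 0)
  expect_true(all(diff(r$d) >= 0))
  expect_true(all(r$d >= 0))

  # identical candidates tie and keep their given order
  dup <- list(b = imgs[[2]], a = imgs[[2]])
  rd <- rank_sites(imgs[[1]], dup, model = model)
  expect_equal(rd$label, c("b", "a"))
})

test_that("tidy and glance summarise a fitted model", {
  imgs <- tiny_images(6, seed = 46)
  model <- fit_pca(imgs, n_components = 3)
  td <- tidy(model)
  expect_equal(nrow(td), 3L)
  expect_equal(sum(td$prop_retained), 1)
  gl <- glance(model)
  expect_equal(gl$n_pixels, 9L)
  expect_equal(gl$n_train, 6L)
})
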