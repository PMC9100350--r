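# Independent brute-force oracles. These evaluate the scoring sums with
# explicit nested loops, one placement at a time, sharing no code with the
# package implementation.

oracle_surface <- function(I, T, method, literal = FALSE) {
  H <- nrow(I); W <- ncol(I); h <- nrow(T); w <- ncol(T)
  out <- matrix(NA_real_, H - h + 1, W - w + 1)
  Tm <- mean(T)
  for (y in 0:(H - h)) {
    for (x in 0:(W - w)) {
      win <- I[(y + 1):(y + h), (x + 1):(x + w), drop = FALSE]
      s_tt <- 0; s_ii <- 0; s_ti <- 0; s_sq <- 0
      s_ti2 <- 0; s_cc <- 0; s_cc2 <- 0; s_tptp <- 0; s_ipip <- 0
      Im <- mean(win)
      for (yy in 1:h) for (xx in 1:w) {
        tv <- T[yy, xx]; iv <- win[yy, xx]
        tp <- tv - Tm; ip <- iv - Im
        s_tt <- s_tt + tv^2
        s_ii <- s_ii + iv^2
        s_ti <- s_ti + tv * iv
        s_ti2 <- s_ti2 + (tv * iv)^2
        s_sq <- s_sq + (tv - iv)^2
        s_cc <- s_cc + tp * ip
        s_cc2 <- s_cc2 + (tp * ip)^2
        s_tptp <- s_tptp + tp^2
        s_ipip <- s_ipip + ip^2
      }
      out[y + 1, x + 1] <- if (!literal) {
        switch(method,
          SqDiff        = s_sq,
          SqDiff_Normed = s_sq / sqrt(s_tt * s_ii),
          CCorr         = s_ti,
          CCorr_Normed  = s_ti / sqrt(s_tt * s_ii),
          CCoeff        = s_cc,
          CCoeff_Normed = if (s_tptp * s_ipip == 0) 0
                          else s_cc / sqrt(s_tptp * s_ipip))
      } else {
        switch(method,
          SqDiff        = s_sq,
          SqDiff_Normed = s_sq / (s_tt * s_ii),
          CCorr         = s_ti2,
          CCorr_Normed  = s_ti2 / (s_tt * s_ii),
          CCoeff        = s_cc2,
          CCoeff_Normed = if (s_tptp * s_ipip == 0) 0
                          else s_cc2 / (s_tptp * s_ipip))
      }
    }
  }
  out
}

oracle_pca_distance <- function(m1, m2, rooted = FALSE) {
  stopifnot(identical(dim(m1), dim(m2)))
  acc <- 0
  for (i in seq_len(nrow(m1))) for (j in seq_len(ncol(m1))) {
    acc <- acc + (m1[i, j] - m2[i, j])^2
  }
  if (rooted) sqrt(acc) / nrow(m1) else acc / nrow(m1)
}

# dense covariance eigendecomposition of row-major flattened images
oracle_pca_components <- function(imgs, n) {
  X <- do.call(rbind, lapply(imgs, function(m) as.vector(t(as.matrix(m)))))
  Xc <- sweep(X, 2, colMeans(X))
  S <- crossprod(Xc) / (nrow(X) - 1)
  ev <- eigen(S, symmetric = TRUE)
  list(values = ev$values[seq_len(n)],
       vectors = ev$vectors[, seq_len(n), drop = FALSE])
}

random_test_image <- function(h, w) {
  capacitive_image(matrix(sample(0:255, h * w, replace = TRUE), h, w))
}

all_tm_methods <- c("SqDiff", "SqDiff_Normed", "CCorr", "CCorr_Normed",
                    "CCoeff", "CCoeff_Normed")

tiny_images <- function(n, h = 3, w = 3, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) random_test_image(h, w))
}
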