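flatten_row_major <- function(img) as.vector(t(as_pixel_matrix(img)))

#' Fit a PCA model to an image collection
#'
#' Flattens each image row-major to a vector, centres by the collection
#' mean, and takes the top eigendirections of the sample covariance (via
#' the singular value decomposition of the centred data matrix — exact and
#' deterministic, no randomised solver). Components are unit-norm, mutually
#' orthogonal, ordered by decreasing explained variance, and given a fixed
#' sign convention: the largest-magnitude coordinate of each component is
#' made positive.
#'
#' @param images List of [capacitive_image()]s (or numeric matrices) of
#'   identical dimensions; at least 2.
#' @param n_components Number of components to keep; at most the rank of
#'   the centred collection (which is at most `length(images) - 1`).
#'   Default `min(8, rank)`.
#' @return A `pca_model`: list with `mean` (length-p vector), `components`
#'   (`n_components x p` matrix), `var_explained`, `n_components`,
#'   `img_dim`, `n_train`.
#' @export
fit_pca <- function(images, n_components = NULL) {
  stopifnot(is.list(images), length(images) >= 2L)
  dims <- lapply(images, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L) {
    abort("all images must have identical dimensions.",
          class = "skincap_size_error")
  }
  X <- do.call(rbind, lapply(images, flatten_row_major))
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc, nu = 0)
  rank <- sum(sv$d > max(sv$d, .Machine$double.eps) * 1e-10)
  rank <- min(rank, nrow(X) - 1L)
  if (is.null(n_components)) n_components <- min(8L, rank)
  if (n_components < 1L || n_components > rank) {
    abort(sprintf("`n_components` must be in [1, %d] (rank of the collection).",
                  rank), class = "skincap_param_error")
  }
  comps <- t(sv$v[, seq_len(n_components), drop = FALSE])
  for (i in seq_len(n_components)) {
    j <- which.max(abs(comps[i, ]))
    if (comps[i, j] < 0) comps[i, ] <- -comps[i, ]
  }
  structure(list(mean = mu, components = comps,
                 var_explained = sv$d[seq_len(n_components)]^2 / (nrow(X) - 1L),
                 n_components = n_components,
                 img_dim = dims[[1]], n_train = nrow(X)),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components over %d x %d px (%d training images)\n",
              x$n_components, x$img_dim[1], x$img_dim[2], x$n_train))
  cat("  explained variance: ",
      paste(signif(x$var_explained, 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @describeIn fit_pca One row per component: its index, explained variance
#'   and proportion of the retained variance.
#' @param x A `pca_model`.
#' @param ... Unused.
#' @export
tidy.pca_model <- function(x, ...) {
  tibble::tibble(component = seq_len(x$n_components),
                 var_explained = x$var_explained,
                 prop_retained = x$var_explained / sum(x$var_explained))
}

#' @describeIn fit_pca One-row model summary.
#' @export
glance.pca_model <- function(x, ...) {
  tibble::tibble(n_components = x$n_components, n_train = x$n_train,
                 n_pixels = prod(x$img_dim),
                 total_var_retained = sum(x$var_explained))
}

#' Project an image onto a PCA model
#'
#' The component representation of an image is the set of per-component
#' contribution vectors: `pc(i, j) = score_i * component_i[j]`, where
#' `score_i` is the coordinate of the centred image along component `i`.
#' Summing the contributions and adding back the model mean gives the best
#' rank-N approximation of the image. Contributions are stored compactly as
#' scores (the components are shared with the model); `as.matrix()` on the
#' result materialises the full `N x p` contribution matrix.
#'
#' @param model A [fit_pca()] model.
#' @param img An image with the model's dimensions.
#' @return A `pca_projection`: list with `scores` (length N), `model`.
#' @export
project <- function(model, img) {
  stopifnot(inherits(model, "pca_model"))
  v <- flatten_row_major(img)
  if (length(v) != length(model$mean)) {
    abort("image dimensions do not match the model.",
          class = "skincap_size_error")
  }
  structure(list(scores = as.vector(model$components %*% (v - model$mean)),
                 model = model),
            class = "pca_projection")
}

#' @export
as.matrix.pca_projection <- function(x, ...) {
  x$model$components * x$scores
}

#' @export
print.pca_projection <- function(x, ...) {
  cat(sprintf("<pca_projection> %d component scores: %s\n",
              length(x$scores),
              paste(signif(head(x$scores, 5), 4), collapse = ", ")))
  invisible(x)
}

#' Reconstruct an image from its projection
#'
#' @param proj A [project()] result.
#' @return Numeric matrix: the rank-N approximation (model mean plus the
#'   summed component contributions), reshaped to the image dimensions.
#' @export
reconstruct <- function(proj) {
  stopifnot(inherits(proj, "pca_projection"))
  v <- proj$model$mean + as.vector(crossprod(proj$model$components, proj$scores))
  matrix(v, proj$model$img_dim[1], proj$model$img_dim[2], byrow = TRUE)
}

#' PCA distance between two images
#'
#' The distance between two component representations,
#' `d = (1/N) * sum_i sum_j (pc1(i,j) - pc2(i,j))^2` by default — the mean
#' (over components) of the squared Euclidean distance between the
#' contribution matrices. Smaller d means more similar images. With
#' `rooted = TRUE` the square root of the double sum is taken before
#' dividing by N, giving a quantity on the image grey-level scale; both
#' versions rank image pairs identically.
#'
#' Because the components are orthonormal, the double sum over contribution
#' matrices equals the sum of squared score differences, which is how the
#' compact projection form is evaluated; explicit matrices are accepted too
#' and summed directly.
#'
#' @param pc1,pc2 Two [project()] results from the same model, or two
#'   numeric matrices of identical shape (components x coordinates).
#' @param rooted Apply the square root before the 1/N factor.
#'   Default `FALSE`.
#' @return Non-negative scalar distance; 0 iff the representations match.
#' @export
pca_distance <- function(pc1, pc2, rooted = FALSE) {
  if (inherits(pc1, "pca_projection") && inherits(pc2, "pca_projection")) {
    if (length(pc1$scores) != length(pc2$scores)) {
      abort("projections come from models with different numbers of components.",
            class = "skincap_size_error")
    }
    ss <- sum((pc1$scores - pc2$scores)^2)
    n <- length(pc1$scores)
  } else {
    m1 <- as.matrix(pc1); m2 <- as.matrix(pc2)
    if (!identical(dim(m1), dim(m2))) {
      abort("component representations have mismatched shapes.",
            class = "skincap_size_error")
    }
    ss <- sum((m1 - m2)^2)
    n <- nrow(m1)
  }
  if (rooted) sqrt(ss) / n else ss / n
}

#' Rank candidate images by PCA distance to a reference
#'
#' Projects the reference and every candidate onto the model and sorts the
#' candidates by ascending distance. Ties keep the candidates' given order.
#' If the reference itself is among the candidates it ranks first with
#' distance 0.
#'
#' @param reference Reference image.
#' @param candidates Named list of images (names become labels).
#' @param model A [fit_pca()] model; default fits one to
#'   `c(list(reference), candidates)`.
#' @param rooted Passed to [pca_distance()].
#' @return Tibble with `label` and `d`, ascending in `d`.
#' @export
rank_sites <- function(reference, candidates, model = NULL, rooted = FALSE) {
  stopifnot(is.list(candidates), length(candidates) >= 1L)
  if (is.null(names(candidates))) {
    names(candidates) <- as.character(seq_along(candidates))
  }
  if (is.null(model)) model <- fit_pca(c(list(reference), unname(candidates)))
  ref_pc <- project(model, reference)
  d <- vapply(candidates,
              function(img) pca_distance(ref_pc, project(model, img),
                                         rooted = rooted),
              numeric(1))
  tibble::tibble(label = names(candidates), d = unname(d)) |>
    dplyr::arrange(.data$d)
}
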