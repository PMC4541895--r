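# Principal component analysis via the scatter matrix.
#
# The projection basis comes from the eigendecomposition of
# S = sum_j (x_j - m)(x_j - m)^T  (n times the population covariance),
# keeping the I eigenvectors of largest eigenvalue.

#' Mean vector of a feature dataset
#'
#' Arithmetic per-feature mean over all samples, ignoring class labels.
#'
#' @param x Numeric matrix, samples in rows.
#' @return Numeric vector of column means.
#' @export
mean_vector <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 1L) stop("dataset is empty")
  colMeans(x)
}

#' Scatter matrix of a feature dataset
#'
#' `S = sum_j (x_j - m)(x_j - m)^T`: symmetric positive semi-definite,
#' equal to n times the population covariance matrix.
#'
#' @param x Numeric matrix, samples in rows.
#' @param m Mean vector; recomputed when omitted.
#' @return p x p scatter matrix.
#' @export
scatter_matrix <- function(x, m = mean_vector(x)) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("scatter matrix needs at least 2 samples")
  xc <- sweep(x, 2L, m)
  s <- crossprod(xc)
  (s + t(s)) / 2  # enforce exact symmetry against rounding
}

#' Eigendecomposition of a scatter matrix
#'
#' Real symmetric eigensolve with eigenvalues sorted non-increasing,
#' orthonormal eigenvectors, tiny negative eigenvalues (> -1e-10 relative)
#' clipped to zero, and a deterministic sign convention: each vector's
#' largest-magnitude component (first such on ties) is made positive.
#'
#' @param s Symmetric matrix.
#' @return List with `values` and `vectors` (columns).
#' @export
principal_axes <- function(s) {
  s <- as.matrix(s)
  if (!isTRUE(all.equal(s, t(s), tolerance = 1e-8))) {
    stop("scatter matrix must be symmetric")
  }
  e <- eigen((s + t(s)) / 2, symmetric = TRUE)
  scale <- max(abs(e$values), 1)
  vals <- e$values
  vals[vals < 0 & vals > -1e-10 * scale] <- 0
  vecs <- apply(e$vectors, 2L, function(v) {
    j <- which.max(abs(v))
    if (v[j] < 0) -v else v
  })
  list(values = vals, vectors = vecs)
}

#' Transformation matrix from the top-I eigenvectors
#'
#' @param axes Eigenpairs from [principal_axes()].
#' @param n_components Number I of leading axes to keep, 1 <= I <= p.
#' @return p x I matrix whose unit-norm columns are the leading axes.
#' @export
projection_matrix <- function(axes, n_components) {
  p <- nrow(axes$vectors)
  if (n_components < 1L || n_components > p) {
    stop("n_components must lie in [1, ", p, "]")
  }
  axes$vectors[, seq_len(n_components), drop = FALSE]
}

#' Fit a PCA model
#'
#' @param x Numeric matrix of samples (rows) by features (columns).
#' @param n_components Number of axes to retain (default 22, the operating
#'   point used throughout the package).
#' @param center Subtract the mean before projecting (default TRUE). With
#'   `center = FALSE` the raw samples are projected; for the downstream
#'   Gaussian classifier the two are equivalent since a common shift moves
#'   every class mean equally, but centering matches the frame in which
#'   the scatter matrix is computed.
#' @return A `pca_model`: mean, eigenvalues, rotation (p x I), settings.
#' @export
fit_pca <- function(x, n_components = 22L, center = TRUE) {
  x <- as.matrix(x)
  m <- mean_vector(x)
  axes <- principal_axes(scatter_matrix(x, m))
  structure(list(mean = m,
                 eigenvalues = axes$values,
                 rotation = projection_matrix(axes, n_components),
                 n_components = as.integer(n_components),
                 center = isTRUE(center),
                 n = nrow(x)),
            class = "pca_model")
}

#' Project samples with a fitted PCA model
#'
#' `y = W^T (x - m)` (or `W^T x` for an uncentered model).
#'
#' @param model A `pca_model`.
#' @param x Vector (one sample) or matrix of samples in rows.
#' @return Matrix of projected samples, n x I.
#' @export
project <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != length(model$mean)) {
    stop("sample dimension ", ncol(x), " does not match model dimension ",
         length(model$mean))
  }
  if (model$center) x <- sweep(x, 2L, model$mean)
  x %*% model$rotation
}

#' @export
print.pca_model <- function(x, ...) {
  total <- sum(x$eigenvalues)
  kept <- sum(x$eigenvalues[seq_len(x$n_components)])
  cat(sprintf(
    "PCA model: %d -> %d dimensions (n = %d, %.1f%% scatter retained)\n",
    length(x$mean), x$n_components, x$n,
    if (total > 0) 100 * kept / total else 100))
  invisible(x)
}

pca_to_list <- function(model) {
  list(mean = as.numeric(model$mean),
       eigenvalues = as.numeric(model$eigenvalues),
       rotation = unname(as.matrix(model$rotation)),
       n_components = model$n_components,
       center = model$center,
       n = model$n)
}

pca_from_list <- function(doc) {
  structure(list(mean = as.numeric(unlist(doc$mean)),
                 eigenvalues = as.numeric(unlist(doc$eigenvalues)),
                 rotation = list_to_matrix(doc$rotation),
                 n_components = as.integer(doc$n_components),
                 center = isTRUE(doc$center),
                 n = as.integer(doc$n)),
            class = "pca_model")
}

list_to_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  do.call(rbind, lapply(x, function(row) as.numeric(unlist(row))))
}
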