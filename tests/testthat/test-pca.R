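# Scatter-matrix PCA: moments, eigenbasis, projection.

random_dataset <- function(n, p, seed) {
  set.seed(seed)
  matrix(rnorm(n * p, sd = rep(seq_len(p), each = n)), n, p)
}

unname_posterior <- function(p) {
  dimnames(p) <- list(NULL, colnames(p))
  p
}

test_that("mean vector is the per-feature arithmetic mean", {
  v <- c(1, -2, 3)
  x <- rbind(v, v, v)
  expect_equal(unname(mean_vector(x)), v)
  a <- c(0, 10, 4); b <- c(2, -10, 0)
  expect_equal(unname(mean_vector(rbind(a, b))), (a + b) / 2)
  set.seed(41)
  for (rep in 1:20) {
    x <- matrix(rnorm(60), 10, 6)
    acc <- rep(0, 6)
    for (i in 1:10) acc <- acc + x[i, ]
    expect_equal(unname(mean_vector(x)), acc / 10)
  }
  expect_error(mean_vector(matrix(numeric(0), 0, 3)), "empty")
})

test_that("scatter matrix is symmetric PSD and equals n x population covariance", {
  x <- random_dataset(50, 8, seed = 43)
  s <- scatter_matrix(x)
  expect_equal(s, t(s))
  expect_equal(s, stats::cov(x) * (nrow(x) - 1), tolerance = 1e-9)
  expect_equal(s / nrow(x),
               stats::cov(x) * (nrow(x) - 1) / nrow(x), tolerance = 1e-9)
  expect_true(all(eigen(s, symmetric = TRUE, only.values = TRUE)$values >
                    -1e-8))
  same <- matrix(rep(c(1, 2, 3), each = 4), 4, 3)
  expect_equal(scatter_matrix(same), matrix(0, 3, 3))
  expect_error(scatter_matrix(x[1, , drop = FALSE]), "at least 2")
})

test_that("principal axes solve the symmetric eigenproblem deterministically", {
  x <- random_dataset(80, 6, seed = 47)
  s <- scatter_matrix(x)
  axes <- principal_axes(s)
  expect_true(all(diff(axes$values) <= 1e-9))
  expect_equal(sum(axes$values), sum(diag(s)), tolerance = 1e-8)
  for (j in seq_along(axes$values)) {
    v <- axes$vectors[, j]
    expect_equal(as.numeric(s %*% v), axes$values[j] * v,
                 tolerance = 1e-8 * max(axes$values))
    expect_equal(sum(v^2), 1)
    expect_gt(v[which.max(abs(v))], 0)  # sign convention
  }
  expect_error(principal_axes(matrix(1:4, 2, 2)), "symmetric")
})

test_that("variance along a single axis is recovered exactly", {
  x <- cbind(c(-2, -1, 0, 1, 2), rep(3, 5))
  axes <- principal_axes(scatter_matrix(x))
  expect_equal(abs(axes$vectors[, 1]), c(1, 0))
  expect_equal(axes$values[2], 0)
})

test_that("projection matrix keeps the top-I unit-norm axes", {
  x <- random_dataset(100, 37, seed = 53)
  axes <- principal_axes(scatter_matrix(x))
  w <- projection_matrix(axes, 22)
  expect_equal(dim(w), c(37L, 22L))
  expect_equal(colSums(w^2), rep(1, 22))
  expect_error(projection_matrix(axes, 0), "n_components")
  expect_error(projection_matrix(axes, 38), "n_components")
})

test_that("the centered projection sends the mean to zero and the full basis is an isometry", {
  x <- random_dataset(60, 12, seed = 59)
  model <- fit_pca(x, n_components = 12)
  expect_equal(as.numeric(project(model, model$mean)), rep(0, 12))
  y <- project(model, x)
  d_x <- as.matrix(stats::dist(x))
  d_y <- as.matrix(stats::dist(y))
  expect_equal(d_y, d_x, tolerance = 1e-8)
  expect_error(project(model, rnorm(5)), "dimension")
})

test_that("reconstruction error is non-increasing in the retained dimension", {
  x <- random_dataset(40, 10, seed = 61)
  m <- mean_vector(x)
  axes <- principal_axes(scatter_matrix(x))
  errs <- vapply(1:10, function(i) {
    w <- projection_matrix(axes, i)
    recon <- sweep(sweep(x, 2, m) %*% w %*% t(w), 2, m, "+")
    sum((x - recon)^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
  # retained scatter equals the sum of the top-I eigenvalues
  for (i in c(2, 5, 10)) {
    w <- projection_matrix(axes, i)
    y <- sweep(x, 2, m) %*% w
    expect_equal(sum(diag(crossprod(y))), sum(axes$values[1:i]),
                 tolerance = 1e-8)
  }
})

test_that("classification after projection is invariant to a common shift", {
  set.seed(67)
  x <- rbind(matrix(rnorm(200, 0), 20),
             matrix(rnorm(200, 4), 20))
  labels <- rep(c("sitting_down", "standing_up"), each = 20)
  shift <- rnorm(10, sd = 5)
  fit_predict <- function(data) {
    model <- train_activity_model(data, labels, n_components = 3,
                                  standardize = FALSE)
    as.character(predict(model, data))
  }
  expect_equal(fit_predict(x), fit_predict(sweep(x, 2, shift, "+")))
})

test_that("PCA models round-trip through the JSON model document", {
  x <- random_dataset(30, 5, seed = 71)
  labels <- rep(activities()[1:2], each = 15)
  model <- train_activity_model(x, labels, n_components = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(model, path)
  back <- read_model(path)
  expect_equal(back$pca$rotation, unname(model$pca$rotation),
               tolerance = 1e-12)
  expect_equal(predict(back, x, type = "posterior"),
               unname_posterior(predict(model, x, type = "posterior")))
})
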