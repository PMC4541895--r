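# The trained activity model: per-feature standardization, scatter-matrix
# PCA, and Gaussian naive Bayes, fitted and applied as one unit.

#' Fit per-feature standardization statistics
#'
#' Raw feature scales differ by orders of magnitude (pressures in [0, 1],
#' spectral peaks in Hz, the phase-sequence code in the thousands), so
#' features are z-scored with training statistics before PCA. The
#' statistics are stored with the model and reapplied at prediction time.
#'
#' @param x Numeric feature matrix.
#' @param sd_floor Lower bound on the per-feature scale.
#' @return List with `center` and `scale` vectors.
#' @export
fit_standardizer <- function(x, sd_floor = 1e-9) {
  x <- as.matrix(x)
  list(center = colMeans(x),
       scale = pmax(apply(x, 2L, stats::sd), sd_floor))
}

#' @rdname fit_standardizer
#' @param standardizer A fitted standardizer.
#' @export
apply_standardizer <- function(standardizer, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  sweep(sweep(x, 2L, standardizer$center), 2L, standardizer$scale, "/")
}

#' Train the full activity-recognition model
#'
#' Standardizes the 37 features, fits PCA on the pooled training samples,
#' projects onto the top `n_components` axes (default 22, the accuracy
#' plateau of the feature-count sweep), and fits the Gaussian naive Bayes
#' on the projections.
#'
#' @param features n x 37 feature matrix (or `feature_corpus`).
#' @param labels Activity label per row (ignored when a corpus is given).
#' @param n_components Retained PCA dimensions.
#' @param standardize Apply z-scoring before PCA (default TRUE).
#' @param ... Passed to [fit_gnb()].
#' @return An `activity_model` bundling standardizer, PCA and GNB.
#' @export
train_activity_model <- function(features, labels = NULL,
                                 n_components = 22L, standardize = TRUE,
                                 ...) {
  if (inherits(features, "feature_corpus")) {
    labels <- features$labels
    features <- features$features
  }
  x <- as.matrix(features)
  std <- if (standardize) fit_standardizer(x) else NULL
  z <- if (standardize) apply_standardizer(std, x) else x
  pca <- fit_pca(z, n_components = n_components)
  y <- project(pca, z)
  gnb <- fit_gnb(y, labels, ...)
  structure(list(standardizer = std, pca = pca, gnb = gnb,
                 n_components = as.integer(n_components)),
            class = "activity_model")
}

#' Predict activities with a trained model
#'
#' @param object An `activity_model`.
#' @param features Feature matrix (rows) or single 37-vector.
#' @param type "class" or "posterior".
#' @param ... Unused.
#' @return Factor of labels or posterior matrix.
#' @export
predict.activity_model <- function(object, features,
                                   type = c("class", "posterior"), ...) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  x <- as.matrix(features)
  z <- if (!is.null(object$standardizer)) {
    apply_standardizer(object$standardizer, x)
  } else {
    x
  }
  predict(object$gnb, project(object$pca, z), type = match.arg(type))
}

#' @export
print.activity_model <- function(x, ...) {
  cat("Activity-recognition model\n")
  print(x$pca)
  print(x$gnb)
  invisible(x)
}

#' Serialize / restore an activity model as JSON
#'
#' The document records the standardization statistics, PCA mean,
#' eigenvalues and rotation, and the per-class Gaussian parameters.
#'
#' @param model An `activity_model`.
#' @param path JSON file path.
#' @export
write_model <- function(model, path) {
  doc <- list(standardizer = model$standardizer,
              pca = pca_to_list(model$pca),
              gnb = gnb_to_list(model$gnb),
              n_components = model$n_components)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path)
  std <- if (!is.null(doc$standardizer)) {
    list(center = as.numeric(unlist(doc$standardizer$center)),
         scale = as.numeric(unlist(doc$standardizer$scale)))
  }
  structure(list(standardizer = std,
                 pca = pca_from_list(doc$pca),
                 gnb = gnb_from_list(doc$gnb),
                 n_components = as.integer(doc$n_components)),
            class = "activity_model")
}

#' Classify a raw stream end to end
#'
#' Normalizes the stream with a calibration profile, runs the fuzzy phase
#' detector on each foot, extracts the 37 features per sample and applies
#' the trained model; emits one label (and posterior) per emitted feature
#' vector.
#'
#' @param stream Raw bilateral stream.
#' @param profile `calibration_profile`.
#' @param model Trained `activity_model`.
#' @return data.frame with time, predicted activity and per-class
#'   posterior columns.
#' @export
classify_stream <- function(stream, profile, model) {
  fv <- pipeline_features(stream, profile)
  x <- as.matrix(fv[feature_names()])
  post <- predict(model, x, type = "posterior")
  out <- data.frame(time = fv$time,
                    activity = predict(model, x, type = "class"))
  cbind(out, as.data.frame(post))
}
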