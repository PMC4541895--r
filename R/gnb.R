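# Gaussian naive Bayes with equal priors and log-domain scoring.
#
# Each class models every feature as an independent Gaussian whose mean
# and population (1/n) standard deviation are the maximum-likelihood
# estimates from that class's training samples. With equal priors the
# evidence term only rescales posteriors, so prediction is the argmax of
# the summed per-feature log densities.

#' The eight recognized foot-movement patterns, in canonical order
#'
#' The fixed ordering also defines the tie-break for exactly tied
#' classifier scores (lowest index wins).
#'
#' @return Character vector of activity labels.
#' @export
activities <- function() {
  c("walking_forward", "walking_backwards", "lateral_left", "lateral_right",
    "turning_left", "turning_right", "sitting_down", "standing_up")
}

#' Fit a Gaussian naive Bayes model
#'
#' @param x Numeric matrix of (projected) samples in rows.
#' @param labels Class label per sample; factor level order is preserved
#'   (character input is ordered by [activities()] when all labels belong
#'   to that set, otherwise by first appearance).
#' @param var_floor Lower bound applied to every per-class standard
#'   deviation, guarding degenerate (constant-within-class) features such
#'   as the phase-sequence code; in standardized-feature units.
#' @param variance "ml" (default) divides squared deviations by n, the
#'   maximum-likelihood estimate; "unbiased" divides by n - 1.
#' @return A `gnb_model` with per-class mean and sd matrices (K x I).
#' @export
fit_gnb <- function(x, labels, var_floor = 1e-9,
                    variance = c("ml", "unbiased")) {
  variance <- match.arg(variance)
  x <- as.matrix(x)
  labels <- as_activity_factor(labels)
  if (nrow(x) != length(labels)) stop("labels must match rows of x")
  counts <- table(labels)
  if (any(counts < 2L)) {
    stop("class(es) with fewer than 2 samples: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  }
  classes <- levels(labels)
  k <- length(classes)
  mu <- matrix(NA_real_, k, ncol(x), dimnames = list(classes, colnames(x)))
  sigma <- mu
  for (j in seq_len(k)) {
    xk <- x[labels == classes[j], , drop = FALSE]
    n <- nrow(xk)
    mu[j, ] <- colMeans(xk)
    ss <- colSums(sweep(xk, 2L, mu[j, ])^2)
    denom <- if (variance == "ml") n else n - 1L
    sigma[j, ] <- pmax(sqrt(ss / denom), var_floor)
  }
  structure(list(classes = classes, mean = mu, sd = sigma,
                 var_floor = var_floor, variance = variance,
                 n_features = ncol(x)),
            class = "gnb_model")
}

as_activity_factor <- function(labels) {
  if (is.factor(labels)) return(droplevels(labels))
  labels <- as.character(labels)
  lev <- if (all(labels %in% activities())) {
    intersect(activities(), unique(labels))
  } else {
    unique(labels)
  }
  factor(labels, levels = lev)
}

#' Log-score of samples under each class model
#'
#' For sample y and class k:
#' `sum_i [ -ln(sd_ik * sqrt(2*pi)) - ((y_i - mu_ik)/sd_ik)^2 / 2 ]`,
#' the log of the product of the per-feature Gaussian densities. With
#' equal priors this is the quantity whose argmax is the prediction.
#'
#' @param model A `gnb_model`.
#' @param x Vector (one sample) or matrix of samples in rows.
#' @return n x K matrix of log-scores.
#' @export
class_log_score <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != model$n_features) {
    stop("expected ", model$n_features, " features, got ", ncol(x))
  }
  if (any(!is.finite(x))) stop("non-finite feature value")
  scores <- matrix(NA_real_, nrow(x), length(model$classes),
                   dimnames = list(NULL, model$classes))
  for (j in seq_along(model$classes)) {
    mu <- model$mean[j, ]
    sd <- model$sd[j, ]
    z <- sweep(x, 2L, mu) / rep(sd, each = nrow(x))
    scores[, j] <- -sum(log(sd * sqrt(2 * pi))) - 0.5 * rowSums(z^2)
  }
  scores
}

#' Predict foot-movement classes
#'
#' The label is the class of maximal log-score (lowest class index on an
#' exact tie). Posteriors are the softmax of the log-scores (equal priors;
#' max-subtracted for numerical stability) and sum to 1 per sample.
#'
#' @param object A `gnb_model`.
#' @param x Samples (vector or matrix).
#' @param type "class" for labels, "posterior" for the probability matrix.
#' @param ... Unused.
#' @return Factor of labels, or an n x K posterior matrix.
#' @export
predict.gnb_model <- function(object, x, type = c("class", "posterior"),
                              ...) {
  type <- match.arg(type)
  scores <- class_log_score(object, x)
  if (type == "class") {
    idx <- apply(scores, 1L, which.max)
    return(factor(object$classes[idx], levels = object$classes))
  }
  shifted <- scores - apply(scores, 1L, max)
  w <- exp(shifted)
  w / rowSums(w)
}

#' @export
print.gnb_model <- function(x, ...) {
  cat(sprintf("Gaussian naive Bayes: %d classes x %d features (%s variance)\n",
              length(x$classes), x$n_features,
              if (x$variance == "ml") "1/n" else "1/(n-1)"))
  invisible(x)
}

gnb_to_list <- function(model) {
  list(classes = model$classes,
       mean = unname(as.matrix(model$mean)),
       sd = unname(as.matrix(model$sd)),
       var_floor = model$var_floor,
       variance = model$variance,
       n_features = model$n_features)
}

gnb_from_list <- function(doc) {
  classes <- as.character(unlist(doc$classes))
  mu <- list_to_matrix(doc$mean)
  sd <- list_to_matrix(doc$sd)
  dimnames(mu) <- list(classes, NULL)
  dimnames(sd) <- list(classes, NULL)
  structure(list(classes = classes, mean = mu, sd = sd,
                 var_floor = as.numeric(doc$var_floor),
                 variance = as.character(doc$variance),
                 n_features = as.integer(doc$n_features)),
            class = "gnb_model")
}
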