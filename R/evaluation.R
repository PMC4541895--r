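# Cross-validation, feature-count sweeps, recognition percentages and
# phase-duration summary tables.

#' Six-fold cross-validated classifier accuracy
#'
#' Splits each class's samples into `folds` contiguous blocks (the
#' assignment is deterministic; no shuffling). Per fold, standardization,
#' PCA and the Gaussian naive Bayes are fitted on the remaining blocks of
#' every class and evaluated on the held-out block; accuracy is pooled
#' correct / total over all folds, in percent.
#'
#' @param corpus A `feature_corpus`, or a feature matrix with `labels`.
#' @param n_components Retained PCA dimensions per fold.
#' @param folds Number of folds (default 6). Classes whose size is not
#'   divisible by the fold count are truncated with a warning.
#' @param labels Labels when `corpus` is a plain matrix.
#' @param standardize Passed to [train_activity_model()].
#' @return List with `accuracy` (%), `fold_accuracy`, and the pooled
#'   `confusion` table.
#' @export
six_fold_cv <- function(corpus, n_components = 22L, folds = 6L,
                        labels = NULL, standardize = TRUE) {
  if (inherits(corpus, "feature_corpus")) {
    labels <- corpus$labels
    x <- corpus$features
  } else {
    x <- as.matrix(corpus)
  }
  labels <- as_activity_factor(labels)
  fold_id <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    per <- length(idx) %/% folds
    if (per < 1L) stop("class ", cl, " has fewer samples than folds")
    if (length(idx) %% folds != 0L) {
      warning("class ", cl, " size not divisible by ", folds,
              "; truncating to ", per * folds, " samples")
    }
    keep <- idx[seq_len(per * folds)]
    fold_id[keep] <- rep(seq_len(folds), each = per)
  }
  used <- fold_id > 0L
  correct <- 0L; total <- 0L
  fold_acc <- numeric(folds)
  confusion <- NULL
  for (f in seq_len(folds)) {
    train <- used & fold_id != f
    test <- fold_id == f
    model <- train_activity_model(x[train, , drop = FALSE], labels[train],
                                  n_components = n_components,
                                  standardize = standardize)
    pred <- predict(model, x[test, , drop = FALSE])
    truth <- factor(labels[test], levels = levels(pred))
    hits <- sum(pred == truth)
    fold_acc[f] <- 100 * hits / sum(test)
    correct <- correct + hits
    total <- total + sum(test)
    tab <- table(truth = truth, predicted = pred)
    confusion <- if (is.null(confusion)) tab else confusion + tab
  }
  list(accuracy = 100 * correct / total, fold_accuracy = fold_acc,
       confusion = confusion)
}

#' Cross-validated accuracy over a range of retained dimensions
#'
#' Re-runs the cross-validation for each candidate feature count; the
#' default sweep covers 5 to 37 retained dimensions.
#'
#' @inheritParams six_fold_cv
#' @param i_range Integer vector of dimension counts in [1, 37].
#' @return data.frame with columns n_components and accuracy.
#' @export
accuracy_feature_sweep <- function(corpus, i_range = 5:37, folds = 6L,
                                   labels = NULL) {
  if (any(i_range < 1L) || any(i_range > 37L)) {
    stop("i_range must lie within [1, 37]")
  }
  acc <- vapply(i_range, function(i) {
    six_fold_cv(corpus, n_components = i, folds = folds,
                labels = labels)$accuracy
  }, numeric(1))
  data.frame(n_components = as.integer(i_range), accuracy = acc)
}

#' Recognition percentage of each activity over a trial
#'
#' The share of the trial's duration during which each activity was
#' predicted, in percent. Each prediction covers the interval up to the
#' next prediction; the last one covers one median sample period. The
#' eight percentages always sum to 100.
#'
#' @param predictions Activity label per sample (factor or character).
#' @param time Timestamps in seconds, strictly increasing.
#' @return Named numeric vector over [activities()] summing to 100.
#' @export
recognition_percentages <- function(predictions, time) {
  if (length(predictions) == 0L) stop("empty prediction sequence")
  if (length(predictions) != length(time)) {
    stop("predictions and time must have equal length")
  }
  dt <- if (length(time) > 1L) diff(time) else 1 / 50
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  dur <- c(dt, stats::median(dt))
  total <- sum(dur)
  if (total <= 0) stop("zero-duration trial")
  labs <- as.character(predictions)
  lev <- if (all(labs %in% activities())) activities() else unique(labs)
  pct <- vapply(lev, function(a) 100 * sum(dur[labs == a]) / total,
                numeric(1))
  stats::setNames(pct, lev)
}

#' Per-trial summary in the style of the evaluation tables
#'
#' Mean and population (1/n) standard deviation of a list of per-trial
#' values, with display rounding to whole milliseconds or to two decimals
#' for percentages. The population convention is what reproduces the
#' reference tables' printed dispersion.
#'
#' @param values Numeric per-trial values.
#' @param unit "ms" (round mean/SD to integers) or "percent" (2 decimals).
#' @return A `trial_summary`: mean, sd, and their rounded display forms.
#' @export
trial_summary <- function(values, unit = c("ms", "percent")) {
  unit <- match.arg(unit)
  if (length(values) < 1L || any(!is.finite(values))) {
    stop("values must be a non-empty finite numeric vector")
  }
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  digits <- if (unit == "ms") 0L else 2L
  structure(list(values = values, mean = m, sd = s,
                 mean_display = round(m, digits),
                 sd_display = round(s, digits), unit = unit),
            class = "trial_summary")
}

#' @export
print.trial_summary <- function(x, ...) {
  unit <- if (x$unit == "ms") "ms" else "%"
  cat(sprintf("Avg (+/-SD): %s (+/-%s) %s over %d trials\n",
              format(x$mean_display), format(x$sd_display), unit,
              length(x$values)))
  invisible(x)
}

#' Bundled reference trial tables
#'
#' Plain-text copies of per-trial reference measurements from a published
#' ambulatory-insole gait study, shipped as worked-example inputs:
#' `gait_reference_trials()` returns the per-trial phase-duration
#' deviations (milliseconds, detector minus reference cycle) for the left
#' or right foot; `recognition_reference_trials()` returns per-trial
#' recognition percentages on a straight path ("A") and a turning path
#' ("B").
#'
#' @param side "left" or "right".
#' @return data.frame of per-trial values.
#' @export
gait_reference_trials <- function(side = c("left", "right")) {
  side <- match.arg(side)
  path <- system.file("extdata",
                      paste0("phase_deviation_trials_", side, ".csv"),
                      package = "insolegait", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname gait_reference_trials
#' @export
recognition_reference_trials <- function() {
  path <- system.file("extdata", "recognition_trials.csv",
                      package = "insolegait", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
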