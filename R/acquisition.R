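# Ingestion, smoothing, calibration and normalization of raw insole streams.
#
# A "stream" is a data.frame with one row per (timestamp, side) record:
#   time      seconds, strictly increasing within each side
#   side      "left" or "right"
#   fsr_heel, fsr_5th, fsr_1st, fsr_toe   raw FSR readings (volts or counts)
#   accel_ap, accel_v                     antero-posterior / vertical accel (g)

#' Names of the four FSR channels on an insole
#'
#' Heel, fifth metatarsal, first metatarsal and hallux (toe), matching the
#' sensor layout the gait-phase rules are written against.
#'
#' @return Character vector of the four channel column names.
#' @export
fsr_channels <- function() {
  c("fsr_heel", "fsr_5th", "fsr_1st", "fsr_toe")
}

accel_channels <- function() {
  c("accel_ap", "accel_v")
}

stream_columns <- function() {
  c("time", "side", fsr_channels(), accel_channels())
}

#' Validate an insole sample stream
#'
#' Checks the column contract, strictly increasing timestamps per side, and
#' that FSR readings are non-negative (negative readings indicate corrupt
#' records and are rejected rather than clamped).
#'
#' @param stream data.frame with the stream columns (see [fsr_channels()]).
#' @return The stream, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_stream <- function(stream) {
  if (!is.data.frame(stream) || nrow(stream) == 0L) {
    stop("stream must be a non-empty data.frame")
  }
  missing <- setdiff(stream_columns(), names(stream))
  if (length(missing) > 0L) {
    stop("stream is missing columns: ", paste(missing, collapse = ", "))
  }
  if (!all(stream$side %in% c("left", "right"))) {
    stop("side must be 'left' or 'right'")
  }
  for (s in unique(stream$side)) {
    tt <- stream$time[stream$side == s]
    if (length(tt) > 1L && any(diff(tt) <= 0)) {
      stop("timestamps must be strictly increasing within the ", s, " stream")
    }
  }
  fsr <- as.matrix(stream[fsr_channels()])
  if (any(!is.finite(fsr))) stop("non-finite FSR reading in stream")
  if (any(fsr < 0)) stop("negative FSR reading: corrupt sample rejected")
  invisible(stream)
}

#' Exponential moving-average low-pass filter
#'
#' Single-pole recursive smoother y[t] = a*x[t] + (1-a)*y[t-1], applied
#' independently to each sensor channel of each side. The first output
#' equals the first input; a coefficient of 1 is the identity. Output is a
#' convex combination of past inputs, so it never leaves the input envelope.
#'
#' @param stream An insole stream (see [validate_stream()]).
#' @param coefficient Smoothing coefficient in (0, 1]; smaller is smoother.
#' @return A stream of the same shape with smoothed sensor channels.
#' @export
low_pass_filter <- function(stream, coefficient = 0.3) {
  validate_stream(stream)
  if (!is.numeric(coefficient) || length(coefficient) != 1L ||
      is.na(coefficient) || coefficient <= 0 || coefficient > 1) {
    stop("coefficient must be a single number in (0, 1]")
  }
  out <- stream
  chans <- c(fsr_channels(), accel_channels())
  for (s in unique(stream$side)) {
    idx <- which(stream$side == s)
    for (ch in chans) {
      out[[ch]][idx] <- ema_filter(stream[[ch]][idx], coefficient)
    }
  }
  out
}

# y[t] = a x[t] + (1-a) y[t-1], y[1] = x[1].  Written as a one-pole
# stats::filter recursion for speed on long streams.
ema_filter <- function(x, a) {
  n <- length(x)
  if (n == 1L || a == 1) return(x)
  y <- stats::filter(a * x[-1L], filter = 1 - a, method = "recursive",
                     init = x[1L])
  c(x[1L], as.numeric(y))
}

#' Estimate the effective range of one FSR channel
#'
#' Two-stage calibration: the first quartile of the unloaded readings gives
#' the channel minimum, and the first quartile of the fully loaded readings
#' gives the maximum. Quartiles use linear interpolation between order
#' statistics (the classical "type 7" convention; see
#' [calibration_quantile_type()]).
#'
#' @param unloaded Numeric readings taken with the foot off the ground.
#' @param loaded Numeric readings taken with full body weight applied.
#' @param channel Channel name, used in error messages.
#' @return Named numeric vector c(min =, max =).
#' @export
estimate_effective_range <- function(unloaded, loaded, channel = "fsr") {
  if (length(unloaded) < 4L || length(loaded) < 4L) {
    stop("need at least 4 readings per calibration stage for ", channel)
  }
  if (any(!is.finite(unloaded)) || any(!is.finite(loaded))) {
    stop("non-finite calibration reading for ", channel)
  }
  q <- calibration_quantile_type()
  lo <- as.numeric(stats::quantile(unloaded, probs = 0.25, type = q))
  hi <- as.numeric(stats::quantile(loaded, probs = 0.25, type = q))
  if (lo >= hi) {
    stop("calibration failure for channel '", channel,
         "': unloaded Q1 (", signif(lo, 4), ") >= loaded Q1 (",
         signif(hi, 4), ")")
  }
  c(min = lo, max = hi)
}

#' Quantile convention used by calibration
#'
#' A single named constant so the order-statistic interpolation scheme can
#' be swapped package-wide; 7 is R's default linear-interpolation type.
#'
#' @return Integer quantile type passed to [stats::quantile()].
#' @export
calibration_quantile_type <- function() 7L

#' Calibrate a full per-side, per-channel profile
#'
#' @param unloaded,loaded Streams (or data.frames with side + FSR columns)
#'   recorded during the unloaded and loaded calibration stages.
#' @return A `calibration_profile`: list keyed by side, then channel, each
#'   entry a c(min, max) effective range.
#' @export
calibrate_profile <- function(unloaded, loaded) {
  sides <- sort(unique(c(unloaded$side, loaded$side)))
  profile <- list()
  for (s in sides) {
    entry <- list()
    for (ch in fsr_channels()) {
      entry[[ch]] <- estimate_effective_range(
        unloaded[[ch]][unloaded$side == s],
        loaded[[ch]][loaded$side == s],
        channel = paste(s, ch, sep = "/"))
    }
    profile[[s]] <- entry
  }
  structure(profile, class = "calibration_profile")
}

#' @export
print.calibration_profile <- function(x, ...) {
  cat("Calibration profile (first-quartile effective ranges)\n")
  for (s in names(x)) {
    for (ch in names(x[[s]])) {
      cat(sprintf("  %-5s %-8s [%.4g, %.4g]\n", s, ch,
                  x[[s]][[ch]]["min"], x[[s]][[ch]]["max"]))
    }
  }
  invisible(x)
}

#' Normalize a raw stream into [0, 1] FSR units
#'
#' Maps each FSR reading through (x - min) / (max - min) using the side's
#' calibration entry and clamps to [0, 1]; saturated sensors therefore map
#' to exactly 0 or 1. Accelerations pass through unchanged.
#'
#' @param stream Raw insole stream.
#' @param profile A `calibration_profile` covering every side present.
#' @return Stream of the same shape with FSR channels in [0, 1].
#' @export
normalize_stream <- function(stream, profile) {
  validate_stream(stream)
  out <- stream
  for (s in unique(stream$side)) {
    entry <- profile[[s]]
    if (is.null(entry)) stop("calibration profile has no entry for side ", s)
    idx <- which(stream$side == s)
    for (ch in fsr_channels()) {
      rng <- entry[[ch]]
      if (is.null(rng)) stop("profile missing channel ", ch, " for side ", s)
      z <- (stream[[ch]][idx] - rng["min"]) / (rng["max"] - rng["min"])
      out[[ch]][idx] <- pmin(1, pmax(0, z))
    }
  }
  out
}

# ---- stream / profile I/O ---------------------------------------------------

#' Read and write insole streams
#'
#' CSV files must carry a header row with the stream columns; JSON-lines
#' files hold one record object per line.
#'
#' @param path File path; format chosen by extension (.csv vs .jsonl/.ndjson)
#'   unless `format` is given.
#' @param format "csv" or "jsonl".
#' @return `read_stream` returns a validated stream data.frame.
#' @export
read_stream <- function(path, format = stream_format(path)) {
  stream <- switch(format,
    csv = utils::read.csv(path, stringsAsFactors = FALSE),
    jsonl = jsonlite::stream_in(file(path), verbose = FALSE),
    stop("unknown stream format: ", format))
  validate_stream(stream)
  stream[, intersect(c(stream_columns(), names(stream)), names(stream))]
}

#' @rdname read_stream
#' @param stream Stream to write.
#' @export
write_stream <- function(stream, path, format = stream_format(path)) {
  switch(format,
    csv = utils::write.csv(stream, path, row.names = FALSE),
    jsonl = jsonlite::stream_out(stream, file(path), verbose = FALSE),
    stop("unknown stream format: ", format))
  invisible(path)
}

stream_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("jsonl", "ndjson", "json")) "jsonl" else "csv"
}

#' Read and write calibration profiles as JSON
#'
#' The document is keyed by side, then channel, each holding min and max.
#'
#' @param profile A `calibration_profile`.
#' @param path File path.
#' @export
write_profile <- function(profile, path) {
  doc <- lapply(profile, function(entry) lapply(entry, as.list))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  doc <- jsonlite::read_json(path)
  profile <- lapply(doc, function(entry) {
    lapply(entry, function(rng) c(min = rng$min, max = rng$max))
  })
  structure(profile, class = "calibration_profile")
}
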