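# 37-dimensional feature extraction over 128-sample ring buffers.
#
# Twelve buffers (8 FSR + 4 acceleration channels across both feet) each
# yield three features: time-domain mean (F1), root-mean-square (F2) and
# dominant non-DC frequency in Hz (F3). Feature 37 is the base-10
# gait-phase-sequence code built from the last four phase activations.

FFT_BUFFER <- 128L

#' Feature-extraction constants
#'
#' Buffers hold 128 samples (about 2.5 s at 50 Hz), so the first vector is
#' emitted at sample 128; the spectral bin width is 50/128 Hz.
#'
#' @return Named list with buffer_size, warmup (127) and sample_rate_hz.
#' @export
feature_constants <- function() {
  list(buffer_size = FFT_BUFFER, warmup = FFT_BUFFER - 1L, sample_rate_hz = 50)
}

#' Canonical feature-channel ordering
#'
#' Left FSRs (heel, 5th, 1st, toe), right FSRs, left accelerations (AP,
#' vertical), right accelerations; F1–F3 within each channel, with the
#' phase-sequence code as the final 37th feature.
#'
#' @return Character vector of the 12 channel ids.
#' @export
feature_channel_order <- function() {
  c(paste0("left_", fsr_channels()), paste0("right_", fsr_channels()),
    paste0("left_", accel_channels()), paste0("right_", accel_channels()))
}

#' @rdname feature_channel_order
#' @return `feature_names()` returns all 37 feature column names.
#' @export
feature_names <- function() {
  c(as.vector(t(outer(feature_channel_order(), c("_mean", "_rms", "_domfreq"),
                      paste0))),
    "phase_seq_code")
}

#' One-sided spectral magnitudes of a full buffer
#'
#' Magnitudes of DFT bins 0..64 of a 128-sample buffer; bin width
#' 50/128 Hz. No window is applied (rectangular) unless `window = "hann"`.
#'
#' @param x Numeric buffer of exactly 128 samples.
#' @param window "rectangular" (default) or "hann".
#' @return 65 non-negative magnitudes.
#' @export
spectral_magnitudes <- function(x, window = c("rectangular", "hann")) {
  window <- match.arg(window)
  if (length(x) != FFT_BUFFER) {
    stop("buffer must hold exactly ", FFT_BUFFER, " samples")
  }
  if (window == "hann") {
    n <- FFT_BUFFER
    x <- x * 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1L) / n))
  }
  Mod(stats::fft(x))[1:(FFT_BUFFER / 2 + 1L)]
}

# Dominant non-DC frequency from a one-sided magnitude spectrum. A flat
# (DC-only) spectrum has no meaningful peak and returns the 0 Hz sentinel.
dominant_frequency <- function(mags, fs = 50) {
  nonDC <- mags[-1L]
  k <- which.max(nonDC)
  if (nonDC[k] <= 1e-9 * max(mags[1L], 1)) return(0)
  k * fs / FFT_BUFFER
}

#' Per-buffer features: mean, RMS and dominant frequency
#'
#' @param x Numeric buffer of exactly 128 samples.
#' @inheritParams spectral_magnitudes
#' @return Named numeric vector c(mean, rms, domfreq).
#' @export
buffer_features <- function(x, window = "rectangular") {
  mags <- spectral_magnitudes(x, window)
  c(mean = mean(x), rms = sqrt(mean(x^2)),
    domfreq = dominant_frequency(mags))
}

#' Gait-phase-sequence code (Feature 4)
#'
#' Encodes the last (up to) four phase activations as a base-10 natural
#' number with digit map LR=1, MSt=2, TSt=3, PSw=4, Sw=5, oldest activation
#' in the most significant digit. Fewer than four activations leave
#' implicit leading zeros; an empty buffer encodes 0.
#'
#' @param phases Character vector of at most 4 phase codes, chronological.
#' @return A single natural number in [0, 5555].
#' @export
phase_sequence_code <- function(phases) {
  if (length(phases) == 0L) return(0)
  if (length(phases) > 4L) stop("phase sequence buffer holds at most 4 phases")
  digits <- match(phases, gait_phases())
  if (any(is.na(digits))) stop("unknown gait phase in sequence buffer")
  sum(digits * 10^(rev(seq_along(digits)) - 1L))
}

# ---- streaming state --------------------------------------------------------

#' Create streaming feature-extraction state
#'
#' Holds one 128-sample ring buffer per signal channel plus the four-slot
#' phase-activation buffer. Update it sample by sample with
#' [update_feature_state()] and read vectors with
#' [extract_feature_vector()]; [featurize_stream()] is the fast vectorized
#' equivalent for recorded streams.
#'
#' @param phase_foot Which foot's activation sequence feeds the
#'   phase-sequence code: "left" (default) or "right".
#' @return A `feature_state` environment.
#' @export
new_feature_state <- function(phase_foot = c("left", "right")) {
  state <- new.env(parent = emptyenv())
  state$buffers <- lapply(stats::setNames(nm = feature_channel_order()),
                          function(ch) numeric(0))
  state$phase_seq <- character(0)
  state$last_phase <- NA_character_
  state$phase_foot <- match.arg(phase_foot)
  state$n_seen <- 0L
  class(state) <- "feature_state"
  state
}

#' Advance streaming state by one bilateral sample
#'
#' Pushes the 12 channel readings into their ring buffers (evicting the
#' oldest value once full) and appends to the phase buffer only when the
#' chosen foot's active phase changes.
#'
#' @param state A `feature_state`.
#' @param left,right Named lists/rows with the FSR and acceleration
#'   channels for each foot.
#' @param left_phase,right_phase Active gait phase per foot.
#' @return The state, invisibly (updated in place).
#' @export
update_feature_state <- function(state, left, right,
                                 left_phase = NA, right_phase = NA) {
  for (ch in c(fsr_channels(), accel_channels())) {
    push_ring(state, paste0("left_", ch), as.numeric(left[[ch]]))
    push_ring(state, paste0("right_", ch), as.numeric(right[[ch]]))
  }
  phase <- if (state$phase_foot == "left") left_phase else right_phase
  if (!is.na(phase) && !identical(phase, state$last_phase)) {
    state$phase_seq <- utils::tail(c(state$phase_seq, phase), 4L)
    state$last_phase <- phase
  }
  state$n_seen <- state$n_seen + 1L
  invisible(state)
}

push_ring <- function(state, ch, value) {
  buf <- c(state$buffers[[ch]], value)
  if (length(buf) > FFT_BUFFER) buf <- buf[-1L]
  state$buffers[[ch]] <- buf
}

#' Extract the 37-feature vector from streaming state
#'
#' @param state A `feature_state` whose buffers are full (128 samples seen).
#' @return Named numeric vector of 37 features, or NULL while warming up.
#' @export
extract_feature_vector <- function(state) {
  if (state$n_seen < FFT_BUFFER) return(NULL)
  values <- unlist(lapply(feature_channel_order(), function(ch) {
    buffer_features(state$buffers[[ch]])
  }), use.names = FALSE)
  stats::setNames(c(values, phase_sequence_code(state$phase_seq)),
                  feature_names())
}

# ---- vectorized extraction --------------------------------------------------

#' Featurize a recorded bilateral stream
#'
#' Computes the per-sample 37-feature vectors for every sample from the
#' 128th onward, equivalent to streaming the samples through
#' [update_feature_state()]/[extract_feature_vector()] but using sliding
#' windows and a batched FFT.
#'
#' @param stream Normalized bilateral stream (both sides present, equal
#'   length, aligned timestamps).
#' @param phases Named list with per-sample active phases `left` and
#'   `right` (as from [active_phases()] on each side's memberships).
#' @param phase_foot Foot whose activation sequence becomes Feature 37.
#' @return data.frame with `time` plus the 37 feature columns.
#' @export
featurize_stream <- function(stream, phases,
                             phase_foot = c("left", "right")) {
  phase_foot <- match.arg(phase_foot)
  left <- stream[stream$side == "left", , drop = FALSE]
  right <- stream[stream$side == "right", , drop = FALSE]
  n <- nrow(left)
  if (n != nrow(right)) stop("left and right streams must have equal length")
  if (n < FFT_BUFFER) {
    stop("stream shorter than the ", FFT_BUFFER, "-sample warm-up")
  }
  chans <- c(fsr_channels(), accel_channels())
  signals <- c(stats::setNames(lapply(chans, function(ch) left[[ch]]),
                               paste0("left_", chans)),
               stats::setNames(lapply(chans, function(ch) right[[ch]]),
                               paste0("right_", chans)))
  feats <- lapply(feature_channel_order(), function(ch) {
    windowed_features(signals[[ch]])
  })
  seq_phase <- phases[[phase_foot]]
  codes <- rolling_phase_codes(seq_phase)[FFT_BUFFER:n]
  out <- data.frame(time = left$time[FFT_BUFFER:n])
  m <- do.call(cbind, feats)
  colnames(m) <- utils::head(feature_names(), -1L)
  out <- cbind(out, as.data.frame(m))
  out$phase_seq_code <- codes
  out
}

# Sliding-window F1/F2/F3 over one signal: windows end at samples 128..n.
windowed_features <- function(x) {
  W <- stats::embed(x, FFT_BUFFER)        # rows: windows, most recent first
  f1 <- rowMeans(W)
  f2 <- sqrt(rowMeans(W^2))
  mags <- Mod(stats::mvfft(t(W)))          # column-wise FFT; order-reversal
  nonDC <- mags[2:(FFT_BUFFER / 2 + 1L), , drop = FALSE]  # leaves Mod intact
  k <- max.col(t(nonDC), ties.method = "first")
  peak <- nonDC[cbind(k, seq_along(k))]
  f3 <- ifelse(peak <= 1e-9 * pmax(mags[1L, ], 1), 0, k * 50 / FFT_BUFFER)
  cbind(f1, f2, f3)
}

# Phase-sequence code active at every sample of a per-sample phase vector.
rolling_phase_codes <- function(phase) {
  r <- rle(phase)
  starts <- cumsum(r$lengths) - r$lengths + 1L
  acts <- r$values
  code_at <- vapply(seq_along(acts), function(a) {
    phase_sequence_code(acts[max(1L, a - 3L):a])
  }, numeric(1))
  code_at[findInterval(seq_along(phase), starts)]
}

#' Write a feature matrix to CSV
#'
#' Columns: timestamp, the 37 features, and (when present) the activity
#' label.
#'
#' @param features data.frame from [featurize_stream()] or a training
#'   corpus table.
#' @param path Output path (.csv or .jsonl).
#' @export
write_features <- function(features, path) {
  if (stream_format(path) == "jsonl") {
    jsonlite::stream_out(features, file(path), verbose = FALSE)
  } else {
    utils::write.csv(features, path, row.names = FALSE)
  }
  invisible(path)
}
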