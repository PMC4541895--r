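# Fuzzy rule-based gait phase detection (GPDA).
#
# Each normalized FSR channel is described by two complementary sigmoid
# fuzzy sets ("low", "high"); one rule per gait phase combines the channel
# grades with the minimum T-norm; the active phase is the argmax grade.

#' The five gait phases, in canonical cycle order
#'
#' Loading response (LR), mid-stance (MSt), terminal stance (TSt),
#' pre-swing (PSw) and swing (Sw). The four stance sub-phases are
#' identifiable from plantar pressure alone; swing is detected as the
#' absence of pressure (its sub-phases are out of scope).
#'
#' @return Character vector of phase codes.
#' @export
gait_phases <- function() {
  c("LR", "MSt", "TSt", "PSw", "Sw")
}

#' Sigmoid membership parameters
#'
#' @param slope Sigmoid steepness s > 0. Default 15; the toe channel uses 50
#'   because toe pressure in pre-swing is brief and its on/off transition is
#'   sharper than at the other sensors.
#' @param inflection Point x0 in (0, 1) where both grades equal 0.5;
#'   default 0.5, keeping the two sets symmetric over the normalized domain.
#' @return A `membership_params` list.
#' @export
membership_params <- function(slope = 15, inflection = 0.5) {
  if (!is.numeric(slope) || slope <= 0) stop("slope must be > 0")
  if (!is.numeric(inflection) || inflection <= 0 || inflection >= 1) {
    stop("inflection must lie in (0, 1)")
  }
  structure(list(slope = slope, inflection = inflection),
            class = "membership_params")
}

#' Default per-channel membership parameters
#'
#' Slope 15 everywhere except the toe channel (slope 50); the steeper toe
#' sigmoid is applied wherever the toe appears as an antecedent.
#'
#' @return Named list of `membership_params`, one per FSR channel.
#' @export
default_membership_params <- function() {
  list(fsr_heel = membership_params(15),
       fsr_5th  = membership_params(15),
       fsr_1st  = membership_params(15),
       fsr_toe  = membership_params(50))
}

check_unit_interval <- function(x) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop("normalized readings must lie in [0, 1]; normalize the stream first")
  }
  x
}

#' Fuzzy membership grades of a normalized reading
#'
#' `membership_low(x) = 1 / (1 + exp(s * (x - x0)))` and
#' `membership_high(x) = 1 - membership_low(x)`: two complementary
#' symmetric sigmoids, so the grades sum to exactly 1 over the whole domain.
#'
#' @param x Normalized reading(s) in [0, 1].
#' @param params A `membership_params` object.
#' @return Grade(s) in (0, 1).
#' @export
membership_low <- function(x, params = membership_params()) {
  check_unit_interval(x)
  1 / (1 + exp(params$slope * (x - params$inflection)))
}

#' @rdname membership_low
#' @export
membership_high <- function(x, params = membership_params()) {
  1 - membership_low(x, params)
}

#' The gait-phase fuzzy rule base
#'
#' One rule per phase over the four FSR channels; entries are "low",
#' "high" or NA (the channel is irrelevant to that phase's pressure
#' pattern). The default encodes the stance pressure patterns: heel-only
#' contact in LR, heel + fifth metatarsal in MSt, forefoot (fifth + first
#' metatarsals) without heel in TSt, toe-only push-off in PSw, and no
#' pressure anywhere in Sw.
#'
#' @return data.frame with columns phase, fsr_heel, fsr_5th, fsr_1st,
#'   fsr_toe.
#' @export
default_rulebase <- function() {
  data.frame(
    phase    = gait_phases(),
    fsr_heel = c("high", "high", "low",  "low",  "low"),
    fsr_5th  = c("low",  "high", "high", "low",  "low"),
    fsr_1st  = c("low",  NA,     "high", NA,     "low"),
    fsr_toe  = c("low",  NA,     NA,     "high", "low"),
    stringsAsFactors = FALSE)
}

validate_rulebase <- function(rulebase) {
  need <- c("phase", fsr_channels())
  if (!all(need %in% names(rulebase))) {
    stop("rulebase must have columns: ", paste(need, collapse = ", "))
  }
  if (!setequal(rulebase$phase, gait_phases()) ||
      anyDuplicated(rulebase$phase)) {
    stop("rulebase must contain exactly one rule per gait phase")
  }
  lv <- unlist(rulebase[fsr_channels()])
  if (!all(is.na(lv) | lv %in% c("low", "high"))) {
    stop("rule antecedents must be 'low', 'high' or NA")
  }
  for (i in seq_len(nrow(rulebase))) {
    if (all(is.na(rulebase[i, fsr_channels()]))) {
      stop("rule for ", rulebase$phase[i],
           " has no antecedents (all channels don't-care)")
    }
  }
  invisible(rulebase)
}

#' Evaluate one fuzzy rule from channel membership grades
#'
#' Applies the minimum T-norm over the rule's antecedents: the rule
#' strength is the smallest grade among the channels the rule constrains
#' ("don't-care" channels are excluded). Grades are supplied directly, so
#' worked examples stated in membership units can be reproduced without
#' going through the sigmoids.
#'
#' @param rule One row of a rule base (list or single-row data.frame).
#' @param grade_low,grade_high Named vectors of per-channel "low"/"high"
#'   grades (names from [fsr_channels()]).
#' @return The rule's output membership grade.
#' @export
evaluate_rule <- function(rule, grade_low, grade_high) {
  grades <- numeric(0)
  for (ch in fsr_channels()) {
    level <- rule[[ch]]
    if (length(level) == 0L || is.na(level)) next
    g <- if (level == "low") grade_low[[ch]] else grade_high[[ch]]
    if (is.null(g) || is.na(g)) stop("missing ", level, " grade for ", ch)
    grades <- c(grades, g)
  }
  if (length(grades) == 0L) stop("rule has no antecedents")
  min(grades)
}

#' Infer per-phase membership grades for normalized FSR samples
#'
#' Fuzzifies each channel with its sigmoid pair and evaluates every rule
#' of the rule base with the minimum T-norm.
#'
#' @param fsr Matrix or data.frame of normalized readings with the four
#'   FSR channel columns (one row per sample), or a single named vector.
#' @param rulebase Rule base as from [default_rulebase()].
#' @param params Per-channel membership parameters.
#' @param time Optional timestamp vector carried into the result.
#' @return data.frame of class `phase_memberships` with optional `time`
#'   and one grade column per phase.
#' @export
infer_phase_memberships <- function(fsr,
                                    rulebase = default_rulebase(),
                                    params = default_membership_params(),
                                    time = NULL) {
  validate_rulebase(rulebase)
  if (is.null(dim(fsr))) fsr <- as.data.frame(as.list(fsr))
  fsr <- as.data.frame(fsr)
  low <- list(); high <- list()
  for (ch in fsr_channels()) {
    if (is.null(fsr[[ch]])) stop("missing normalized channel ", ch)
    low[[ch]] <- membership_low(fsr[[ch]], params[[ch]])
    high[[ch]] <- 1 - low[[ch]]
  }
  n <- nrow(fsr)
  out <- data.frame(matrix(NA_real_, n, length(gait_phases())))
  names(out) <- gait_phases()
  for (i in seq_len(nrow(rulebase))) {
    strength <- rep(Inf, n)
    for (ch in fsr_channels()) {
      level <- rulebase[[ch]][i]
      if (is.na(level)) next
      g <- if (level == "low") low[[ch]] else high[[ch]]
      strength <- pmin(strength, g)
    }
    out[[rulebase$phase[i]]] <- strength
  }
  if (!is.null(time)) out <- cbind(time = time, out)
  class(out) <- c("phase_memberships", "data.frame")
  out
}

#' Run the GPDA over a normalized stream for one side
#'
#' Convenience wrapper: selects one side of a normalized bilateral stream
#' and infers phase memberships sample by sample. Each foot is processed by
#' an independent GPDA instance.
#'
#' @param stream Normalized insole stream.
#' @param side "left" or "right".
#' @inheritParams infer_phase_memberships
#' @return A `phase_memberships` data.frame with a `time` column.
#' @export
gpda_memberships <- function(stream, side,
                             rulebase = default_rulebase(),
                             params = default_membership_params()) {
  rows <- stream[stream$side == side, , drop = FALSE]
  if (nrow(rows) == 0L) stop("stream has no samples for side ", side)
  infer_phase_memberships(rows[fsr_channels()], rulebase, params,
                          time = rows$time)
}

#' Per-sample active phase from a membership stream
#'
#' The active phase at each sample is the phase of maximum membership.
#' Exact ties keep the previously active phase when it is among the tied
#' phases, otherwise the earliest phase in cycle order; a tie at the first
#' sample also resolves in cycle order.
#'
#' @param memberships A `phase_memberships` data.frame.
#' @return Character vector of active phase codes, one per sample.
#' @export
active_phases <- function(memberships) {
  g <- as.matrix(as.data.frame(memberships)[gait_phases()])
  n <- nrow(g)
  if (n == 0L) stop("empty membership stream")
  idx <- max.col(g, ties.method = "first")
  rowmax <- g[cbind(seq_len(n), idx)]
  tied <- which(rowSums(g == rowmax) > 1L)
  if (length(tied) > 0L) {
    # keep the previous active phase through exact ties
    for (i in tied) {
      if (i == 1L) next
      prev <- idx[i - 1L]
      if (g[i, prev] == rowmax[i]) idx[i] <- prev
    }
  }
  gait_phases()[idx]
}

#' Demarcate phase events in a membership stream
#'
#' Merges consecutive samples sharing the same active phase into events.
#' Event boundaries sit on sample timestamps: an event starts at its first
#' sample and ends where the next event starts; the final event is closed
#' one nominal sample period after its last sample. An optional debounce
#' merges events shorter than `min_duration_ms` into their predecessor
#' (off by default).
#'
#' @param memberships A `phase_memberships` data.frame with a `time`
#'   column and increasing timestamps.
#' @param min_duration_ms Minimum event duration; 0 disables debouncing.
#' @return data.frame of class `phase_events` with columns phase, start,
#'   end (seconds) and duration_ms.
#' @export
demarcate_phases <- function(memberships, min_duration_ms = 0) {
  if (is.null(memberships$time)) stop("membership stream needs a time column")
  tt <- memberships$time
  if (length(tt) > 1L && any(diff(tt) <= 0)) {
    stop("timestamps must be strictly increasing")
  }
  phase <- active_phases(memberships)
  dt <- if (length(tt) > 1L) stats::median(diff(tt)) else 1 / 50
  r <- rle(phase)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  start <- tt[starts_idx]
  end <- c(tt[starts_idx[-1L]], tt[length(tt)] + dt)
  ev <- data.frame(phase = r$values, start = start, end = end,
                   duration_ms = (end - start) * 1000,
                   stringsAsFactors = FALSE)
  if (min_duration_ms > 0) ev <- debounce_events(ev, min_duration_ms)
  class(ev) <- c("phase_events", "data.frame")
  ev
}

# Merge events shorter than the floor into the preceding event (the first
# event is merged forward), then re-merge adjacent duplicates.
debounce_events <- function(ev, min_duration_ms) {
  repeat {
    short <- which(ev$duration_ms < min_duration_ms)
    if (length(short) == 0L || nrow(ev) == 1L) break
    i <- short[1L]
    absorb <- if (i == 1L) 2L else i - 1L
    ev$phase[i] <- ev$phase[absorb]
    r <- rle(ev$phase)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ev <- data.frame(phase = r$values,
                     start = ev$start[starts],
                     end = ev$end[ends],
                     duration_ms = (ev$end[ends] - ev$start[starts]) * 1000,
                     stringsAsFactors = FALSE)
  }
  ev
}

#' Write or read demarcated phase events
#'
#' CSV columns: phase, start, end, duration_ms and (if present) side.
#'
#' @param events A `phase_events` data.frame.
#' @param path File path (.csv or .jsonl).
#' @export
write_events <- function(events, path) {
  if (stream_format(path) == "jsonl") {
    jsonlite::stream_out(as.data.frame(events), file(path), verbose = FALSE)
  } else {
    utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  }
  invisible(path)
}

# ---- reference cycle --------------------------------------------------------

#' The canonical gait-cycle phase schedule
#'
#' Percentages of total cycle time: LR 10, MSt 20, TSt 20, PSw 10, Sw 40.
#'
#' @return Named numeric vector of percentages summing to 100.
#' @export
reference_schedule <- function() {
  c(LR = 10, MSt = 20, TSt = 20, PSw = 10, Sw = 40)
}

#' Reference duration of a gait phase
#'
#' Converts a phase's share of the cycle into time units:
#' `phase_pct / 100 * cycle_time_ms`.
#'
#' @param phase_pct Percentage of the cycle in [0, 100].
#' @param cycle_time_ms Total cycle duration, milliseconds, > 0.
#' @return Phase duration in milliseconds.
#' @export
reference_phase_duration <- function(phase_pct, cycle_time_ms) {
  if (any(phase_pct < 0) || any(phase_pct > 100)) {
    stop("phase_pct must lie in [0, 100]")
  }
  if (any(cycle_time_ms <= 0)) stop("cycle_time_ms must be positive")
  phase_pct / 100 * cycle_time_ms
}

#' Reference cycle table for a given cycle time
#'
#' @param cycle_time_ms Total cycle duration in milliseconds.
#' @param schedule Named phase percentages (default [reference_schedule()]).
#' @return data.frame with phase, pct and duration_ms.
#' @export
reference_cycle <- function(cycle_time_ms, schedule = reference_schedule()) {
  if (abs(sum(schedule) - 100) > 1e-9) stop("schedule must sum to 100")
  data.frame(phase = names(schedule), pct = as.numeric(schedule),
             duration_ms = reference_phase_duration(as.numeric(schedule),
                                                    cycle_time_ms),
             stringsAsFactors = FALSE)
}

#' Split demarcated events into gait cycles
#'
#' A cycle starts at each LR onset (initial contact) and runs to the next
#' LR onset. Cycles missing any of the five phases are dropped with a
#' warning.
#'
#' @param events A `phase_events` data.frame.
#' @return List of complete-cycle event data.frames.
#' @export
segment_cycles <- function(events) {
  starts <- which(events$phase == "LR")
  if (length(starts) < 2L) return(list())
  cycles <- list()
  dropped <- 0L
  for (k in seq_len(length(starts) - 1L)) {
    cyc <- events[starts[k]:(starts[k + 1L] - 1L), , drop = FALSE]
    if (setequal(unique(cyc$phase), gait_phases())) {
      cycles[[length(cycles) + 1L]] <- cyc
    } else {
      dropped <- dropped + 1L
    }
  }
  if (dropped > 0L) {
    warning(dropped, " incomplete gait cycle(s) excluded from analysis")
  }
  cycles
}

#' Per-phase differences between measured and reference durations
#'
#' For each complete cycle, each phase's measured duration (summed over the
#' cycle's events) is compared with the reference duration computed from
#' that cycle's own total time; differences are averaged across cycles.
#' Positive values mean the detector overestimates the phase.
#'
#' @param events A `phase_events` data.frame (one foot).
#' @param schedule Reference phase percentages.
#' @return Named numeric vector of mean differences in milliseconds.
#' @export
phase_duration_differences <- function(events,
                                       schedule = reference_schedule()) {
  cycles <- segment_cycles(events)
  if (length(cycles) == 0L) stop("no complete gait cycle in events")
  diffs <- vapply(cycles, function(cyc) {
    cycle_time <- sum(cyc$duration_ms)
    measured <- vapply(gait_phases(), function(p) {
      sum(cyc$duration_ms[cyc$phase == p])
    }, numeric(1))
    measured - reference_phase_duration(schedule[gait_phases()], cycle_time)
  }, numeric(length(gait_phases())))
  rowMeans(diffs)
}
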