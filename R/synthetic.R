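# Synthetic insole-signal simulator.
#
# Generates labeled 50 Hz bilateral streams for the eight recognized
# foot-movement patterns, plus calibration recordings, standing in for
# human trial data. Walking traces follow the stance pressure patterns of
# the rule base (heel contact in LR/MSt, fifth metatarsal through
# MSt/TSt, first metatarsal in TSt, toe push-off in PSw, no pressure in
# Sw) on the canonical 10/20/20/10/40 phase schedule, with raised-cosine
# transitions between pressure levels.

#' Simulation parameters
#'
#' @param cadence Steps per minute (two steps per stride); the default 100
#'   gives a 1.2 s gait cycle, a typical adult walking pace.
#' @param cycle_time_ms Gait-cycle duration; derived from `cadence` when
#'   NULL (`120000 / cadence`).
#' @param n_cycles Number of gait cycles to generate.
#' @param noise_sd Gaussian noise, as a fraction of each channel's
#'   normalized signal range (also used, in g, on the accelerations).
#' @param transition_ramp_ms Width of the raised-cosine ramp between
#'   pressure levels; models the soft, continuous transitions of real
#'   plantar loading.
#' @param schedule Phase percentages of the cycle (must sum to 100).
#' @param fs Sampling rate, Hz.
#' @param seed Optional integer; fixes the stream bit-for-bit.
#' @return A `gait_sim_params` list.
#' @export
gait_sim_params <- function(cadence = 100, cycle_time_ms = NULL,
                            n_cycles = 20, noise_sd = 0.05,
                            transition_ramp_ms = 60,
                            schedule = reference_schedule(),
                            fs = 50, seed = NULL) {
  if (is.null(cycle_time_ms)) cycle_time_ms <- 120000 / cadence
  if (abs(sum(schedule) - 100) > 1e-9) stop("schedule must sum to 100")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (cycle_time_ms <= length(schedule) * transition_ramp_ms) {
    stop("cycle_time_ms shorter than the total transition-ramp budget")
  }
  structure(list(cadence = cadence, cycle_time_ms = cycle_time_ms,
                 n_cycles = n_cycles, noise_sd = noise_sd,
                 transition_ramp_ms = transition_ramp_ms,
                 schedule = schedule, fs = fs, seed = seed),
            class = "gait_sim_params")
}

# Simulated sensor electrical ranges (volts): a light contact pressure is
# read even with the foot in the air, and full load saturates below the
# 3.3 V supply; ranges differ slightly per sensor site.
sensor_ranges <- function() {
  list(fsr_heel = c(min = 0.70, max = 3.00),
       fsr_5th  = c(min = 0.80, max = 2.90),
       fsr_1st  = c(min = 0.75, max = 2.95),
       fsr_toe  = c(min = 0.65, max = 2.85))
}

# Normalized pressure-envelope targets per phase (rows) and channel.
# Don't-care channels carry plausible intermediate levels: partial first
# metatarsal load in MSt/PSw and late toe loading through TSt.
phase_envelope_targets <- function() {
  rbind(fsr_heel = c(LR = 1.0, MSt = 1.0, TSt = 0.0, PSw = 0.0, Sw = 0.0),
        fsr_5th  = c(LR = 0.0, MSt = 1.0, TSt = 1.0, PSw = 0.0, Sw = 0.0),
        fsr_1st  = c(LR = 0.0, MSt = 0.3, TSt = 1.0, PSw = 0.3, Sw = 0.0),
        fsr_toe  = c(LR = 0.0, MSt = 0.1, TSt = 0.3, PSw = 1.0, Sw = 0.0))
}

with_sim_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  expr
}

# Raised-cosine smoothing of a stepwise level track. Circular because the
# generated streams are whole numbers of periodic cycles.
smooth_steps <- function(x, ramp_samples, circular = TRUE) {
  l <- max(1L, ramp_samples)
  if (l %% 2L == 0L) l <- l + 1L
  if (l == 1L) return(x)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(l) / (l + 1)))
  w <- w / sum(w)
  if (circular) {
    as.numeric(stats::filter(x, w, sides = 2, circular = TRUE))
  } else {
    pad <- (l - 1L) %/% 2L
    xp <- c(rep(x[1L], pad), x, rep(x[length(x)], pad))
    as.numeric(stats::filter(xp, w, sides = 2))[(pad + 1L):(pad + length(x))]
  }
}

# Per-sample phase labels for one cycle of `spc` samples.
cycle_phase_labels <- function(schedule, spc) {
  bounds <- round(cumsum(schedule) / 100 * spc)
  rep(names(schedule), diff(c(0L, bounds)))
}

# Shared generator for gait-like activities: periodic phase-driven
# pressure envelopes, optionally reversed in time order, with per-side
# amplitude scaling and cycle-locked accelerations.
simulate_gait_like <- function(params, activity,
                               phase_order = gait_phases(),
                               amp = c(left = 1, right = 1),
                               ap_amp = 0.5, ap_mean = 0.05,
                               v_amp = 0.3) {
  fs <- params$fs
  spc <- round(params$cycle_time_ms / 1000 * fs)
  sched <- params$schedule[phase_order]
  labels_cycle <- cycle_phase_labels(sched, spc)
  n <- spc * params$n_cycles
  labels_left <- rep(labels_cycle, params$n_cycles)
  shift <- spc %/% 2L  # feet half a cycle out of phase
  labels_right <- rep(c(labels_cycle[(shift + 1L):spc],
                        labels_cycle[seq_len(shift)]), params$n_cycles)
  ramp <- round(params$transition_ramp_ms / 1000 * fs)
  tt <- (seq_len(n) - 1L) / fs
  f <- 1000 / params$cycle_time_ms
  targets <- phase_envelope_targets()
  with_sim_seed(params$seed, {
    sides <- lapply(c(left = "left", right = "right"), function(s) {
      labels <- if (s == "left") labels_left else labels_right
      phs <- if (s == "left") 0 else pi
      df <- data.frame(time = tt, side = s)
      for (ch in fsr_channels()) {
        env <- amp[[s]] * smooth_steps(targets[ch, labels], ramp)
        env <- env + stats::rnorm(n, 0, params$noise_sd)
        rng <- sensor_ranges()[[ch]]
        df[[ch]] <- rng["min"] +
          pmin(1, pmax(0, env)) * (rng["max"] - rng["min"])
      }
      df$accel_ap <- ap_mean + ap_amp * sin(2 * pi * f * tt + phs) +
        0.2 * ap_amp * sin(4 * pi * f * tt + phs) +
        stats::rnorm(n, 0, params$noise_sd)
      df$accel_v <- 1 + v_amp * sin(4 * pi * f * tt + phs) +
        stats::rnorm(n, 0, params$noise_sd)
      df$phase <- labels
      df$activity <- activity
      df
    })
    interleave_sides(sides$left, sides$right)
  })
}

interleave_sides <- function(left, right) {
  out <- rbind(left, right)
  out[order(out$time, out$side), , drop = FALSE]
}

#' Simulate a clean walking-forward stream with ground-truth phases
#'
#' Left and right feet are half a cycle out of phase; each foot's FSR
#' envelopes follow the stance pressure patterns on the configured phase
#' schedule, and the accelerations are cycle-locked sinusoids.
#'
#' @param params A `gait_sim_params` object.
#' @return Labeled stream: a bilateral raw stream data.frame with extra
#'   `phase` (ground truth) and `activity` columns.
#' @export
simulate_walk_forward <- function(params = gait_sim_params()) {
  simulate_gait_like(params, "walking_forward")
}

#' Simulate one of the eight foot-movement patterns
#'
#' Signatures: walking backwards plays the pressure sequence in reverse
#' (toe-to-heel progression) with reversed forward acceleration; lateral
#' walking loads the whole foot in rhythmic pulses with strong left/right
#' asymmetry and little antero-posterior acceleration; turning walks on a
#' much slower cycle with the pivot foot unloaded; sitting down and
#' standing up are monotone pressure decays/rises with opposite
#' antero-posterior acceleration offsets.
#'
#' @param kind One of [activities()].
#' @param duration_s Stream duration in seconds (gait-like kinds round up
#'   to whole cycles).
#' @param params A `gait_sim_params` object.
#' @return Labeled stream as in [simulate_walk_forward()]; the `phase`
#'   column is NA for patterns without a meaningful gait-phase schedule.
#' @export
simulate_activity <- function(kind, duration_s = 30,
                              params = gait_sim_params()) {
  kind <- match.arg(kind, activities())
  p <- params
  cycles_for <- function(cycle_ms) {
    as.integer(ceiling(duration_s * 1000 / cycle_ms))
  }
  switch(kind,
    walking_forward = {
      p$n_cycles <- cycles_for(p$cycle_time_ms)
      simulate_gait_like(p, kind)
    },
    walking_backwards = {
      p$n_cycles <- cycles_for(p$cycle_time_ms)
      simulate_gait_like(p, kind, phase_order = rev(gait_phases()),
                         ap_mean = -0.05)
    },
    turning_left = ,
    turning_right = {
      p$cycle_time_ms <- 2560  # slow pivoting cycle, ~0.39 Hz fundamental
      p$n_cycles <- cycles_for(p$cycle_time_ms)
      amp <- if (kind == "turning_left") {
        c(left = 0.55, right = 1)   # inner (pivot) foot partially unloaded
      } else {
        c(left = 1, right = 0.55)
      }
      simulate_gait_like(p, kind, amp = amp, ap_amp = 0.3, ap_mean = 0.02)
    },
    lateral_left = ,
    lateral_right = simulate_lateral(kind, duration_s, p),
    sitting_down = ,
    standing_up = simulate_posture_change(kind, duration_s, p))
}

# Lateral walking: all four FSRs pulse together at 0.781 Hz; the leading
# foot carries most of the load. AP acceleration is nearly absent.
simulate_lateral <- function(kind, duration_s, params) {
  fs <- params$fs
  period <- 64L  # samples -> 0.78125 Hz, an exact spectral bin
  n <- as.integer(ceiling(duration_s * fs / period)) * period
  tt <- (seq_len(n) - 1L) / fs
  f <- fs / period
  amp <- if (kind == "lateral_left") {
    c(left = 0.9, right = 0.45)
  } else {
    c(left = 0.45, right = 0.9)
  }
  with_sim_seed(params$seed, {
    sides <- lapply(c(left = "left", right = "right"), function(s) {
      phs <- if (s == "left") 0 else pi
      pulse <- amp[[s]] * (0.5 + 0.5 * sin(2 * pi * f * tt + phs))
      df <- data.frame(time = tt, side = s)
      for (ch in fsr_channels()) {
        env <- pulse + stats::rnorm(n, 0, params$noise_sd)
        rng <- sensor_ranges()[[ch]]
        df[[ch]] <- rng["min"] +
          pmin(1, pmax(0, env)) * (rng["max"] - rng["min"])
      }
      df$accel_ap <- 0.1 * sin(2 * pi * f * tt + phs) +
        stats::rnorm(n, 0, params$noise_sd)
      df$accel_v <- 1 + 0.4 * sin(2 * pi * f * tt + phs) +
        stats::rnorm(n, 0, params$noise_sd)
      df$phase <- NA_character_
      df$activity <- kind
      df
    })
    interleave_sides(sides$left, sides$right)
  })
}

# Sitting down / standing up: a single sigmoidal load transfer across the
# stream with opposite AP acceleration offsets and a vertical transient.
simulate_posture_change <- function(kind, duration_s, params) {
  fs <- params$fs
  n <- as.integer(round(duration_s * fs))
  tt <- (seq_len(n) - 1L) / fs
  mid <- duration_s / 2
  ramp <- 1 / 2  # ~2 s sigmoidal transfer
  level <- 1 / (1 + exp((tt - mid) / ramp))
  sign <- if (kind == "sitting_down") 1 else -1
  if (kind == "standing_up") level <- 1 - level
  ap_mean <- if (kind == "sitting_down") -0.15 else 0.15
  bump <- exp(-((tt - mid) / 0.6)^2)
  with_sim_seed(params$seed, {
    sides <- lapply(c(left = "left", right = "right"), function(s) {
      df <- data.frame(time = tt, side = s)
      for (ch in fsr_channels()) {
        env <- level + stats::rnorm(n, 0, params$noise_sd)
        rng <- sensor_ranges()[[ch]]
        df[[ch]] <- rng["min"] +
          pmin(1, pmax(0, env)) * (rng["max"] - rng["min"])
      }
      df$accel_ap <- ap_mean + stats::rnorm(n, 0, params$noise_sd)
      df$accel_v <- 1 - sign * 0.3 * bump + stats::rnorm(n, 0, params$noise_sd)
      df$phase <- NA_character_
      df$activity <- kind
      df
    })
    interleave_sides(sides$left, sides$right)
  })
}

#' Simulate the two-stage calibration recordings
#'
#' Unloaded readings sit just above each sensor's true minimum and loaded
#' readings just below its maximum, so the first-quartile calibration
#' recovers an effective range inside the simulated sensor range.
#'
#' @param n_readings Readings per stage and channel.
#' @param spread Reading scatter as a fraction of the sensor range.
#' @param seed Optional integer seed.
#' @return List with `unloaded` and `loaded` stream-like data.frames.
#' @export
simulate_calibration <- function(n_readings = 64, spread = 0.03,
                                 seed = NULL) {
  with_sim_seed(seed, {
    stage <- function(which) {
      do.call(rbind, lapply(c("left", "right"), function(s) {
        df <- data.frame(time = (seq_len(n_readings) - 1L) / 50, side = s)
        for (ch in fsr_channels()) {
          rng <- sensor_ranges()[[ch]]
          span <- rng["max"] - rng["min"]
          noise <- abs(stats::rnorm(n_readings, 0, spread * span))
          df[[ch]] <- if (which == "unloaded") {
            rng["min"] + noise
          } else {
            rng["max"] - noise
          }
        }
        df$accel_ap <- 0
        df$accel_v <- 1
        df
      }))
    }
    list(unloaded = stage("unloaded"), loaded = stage("loaded"))
  })
}

#' Build the labeled training corpus
#'
#' Streams each of the eight movement patterns through the full front end
#' (quartile calibration, normalization, fuzzy phase detection, buffer
#' feature extraction) and keeps the first `n_per_class` 37-dimensional
#' vectors per pattern: 1200 each, 9600 in total at the default scale.
#'
#' @param params A `gait_sim_params` object (its seed, when set, derives
#'   independent per-activity stream seeds).
#' @param n_per_class Feature vectors retained per activity.
#' @return A `feature_corpus`: list with `features` (n x 37 matrix),
#'   `labels` (factor) and the generating parameters.
#' @export
build_training_corpus <- function(params = gait_sim_params(seed = 1),
                                  n_per_class = 1200) {
  warmup <- feature_constants()$warmup
  duration <- (n_per_class + warmup) / params$fs + 2 * params$cycle_time_ms / 1000
  cal <- simulate_calibration(seed = offset_seed(params$seed, 1000L))
  profile <- calibrate_profile(cal$unloaded, cal$loaded)
  feats <- list()
  labels <- character(0)
  for (i in seq_along(activities())) {
    kind <- activities()[i]
    p <- params
    p$seed <- offset_seed(params$seed, i)
    stream <- simulate_activity(kind, duration_s = duration, params = p)
    fv <- pipeline_features(stream, profile)
    if (nrow(fv) < n_per_class) {
      stop("stream too short to emit ", n_per_class, " vectors for ", kind)
    }
    fv <- fv[seq_len(n_per_class), , drop = FALSE]
    feats[[kind]] <- as.matrix(fv[feature_names()])
    labels <- c(labels, rep(kind, n_per_class))
  }
  structure(list(features = do.call(rbind, feats),
                 labels = factor(labels, levels = activities()),
                 n_per_class = n_per_class,
                 params = params),
            class = "feature_corpus")
}

offset_seed <- function(seed, k) {
  if (is.null(seed)) NULL else (seed * 1009L + k) %% 2147483647L
}

# Front-end shared by corpus building and classification: normalize,
# detect phases per foot, featurize.
pipeline_features <- function(stream, profile,
                              rulebase = default_rulebase(),
                              mf_params = default_membership_params()) {
  norm <- normalize_stream(stream[stream_columns()], profile)
  phases <- lapply(c(left = "left", right = "right"), function(s) {
    active_phases(gpda_memberships(norm, s, rulebase, mf_params))
  })
  featurize_stream(norm, phases)
}

#' @export
print.feature_corpus <- function(x, ...) {
  cat(sprintf("Feature corpus: %d samples x %d features, %d per class\n",
              nrow(x$features), ncol(x$features), x$n_per_class))
  print(table(x$labels))
  invisible(x)
}

#' @export
as.data.frame.feature_corpus <- function(x, ...) {
  cbind(data.frame(label = x$labels), as.data.frame(x$features))
}
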