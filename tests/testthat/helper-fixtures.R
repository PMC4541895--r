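# Shared fixtures, built in code. Heavier objects are cached per test run.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (is.null(fixture_cache[[key]])) fixture_cache[[key]] <- build()
  fixture_cache[[key]]
}

# Calibration profile with the simulator's exact sensor ranges, so
# noiseless simulated streams normalize to their ideal envelopes.
true_profile <- function() {
  ranges <- list(fsr_heel = c(min = 0.70, max = 3.00),
                 fsr_5th  = c(min = 0.80, max = 2.90),
                 fsr_1st  = c(min = 0.75, max = 2.95),
                 fsr_toe  = c(min = 0.65, max = 2.85))
  structure(list(left = ranges, right = ranges),
            class = "calibration_profile")
}

# Minimal valid bilateral stream with constant readings.
constant_stream <- function(n = 10, fsr = 1, accel = 0) {
  do.call(rbind, lapply(c("left", "right"), function(s) {
    data.frame(time = (seq_len(n) - 1) / 50, side = s,
               fsr_heel = fsr, fsr_5th = fsr, fsr_1st = fsr, fsr_toe = fsr,
               accel_ap = accel, accel_v = accel)
  }))
}

noiseless_walk <- function(n_cycles = 10, seed = 3) {
  cached(paste0("walk_", n_cycles, "_", seed), function() {
    simulate_walk_forward(gait_sim_params(noise_sd = 0,
                                          n_cycles = n_cycles, seed = seed))
  })
}

default_corpus <- function() {
  cached("corpus_seed1", function() {
    build_training_corpus(gait_sim_params(seed = 1), n_per_class = 1200)
  })
}

small_corpus <- function() {
  cached("corpus_small", function() {
    build_training_corpus(gait_sim_params(seed = 7), n_per_class = 150)
  })
}
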