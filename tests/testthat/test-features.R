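# Ring buffers, spectral features and the phase-sequence code.

fake_sample <- function(v) {
  stats::setNames(as.list(rep(v, 6)), c(fsr_channels(), "accel_ap", "accel_v"))
}

test_that("ring buffers fill to 128 and then evict the oldest value", {
  state <- new_feature_state()
  for (i in 1:129) {
    update_feature_state(state, fake_sample(i), fake_sample(-i), "LR", "LR")
  }
  buf <- state$buffers$left_fsr_heel
  expect_length(buf, 128)
  expect_equal(buf[1], 2)   # value 1 evicted on the 129th update
  expect_equal(buf[128], 129)
})

test_that("no feature vector is emitted during the 127-sample warm-up", {
  state <- new_feature_state()
  for (i in 1:127) {
    update_feature_state(state, fake_sample(0.5), fake_sample(0.5), "Sw", "Sw")
    expect_null(extract_feature_vector(state))
  }
  update_feature_state(state, fake_sample(0.5), fake_sample(0.5), "Sw", "Sw")
  fv <- extract_feature_vector(state)
  expect_length(fv, 37)
  expect_named(fv, feature_names())
})

test_that("a constant active phase never grows the phase buffer", {
  state <- new_feature_state()
  for (i in 1:10) {
    update_feature_state(state, fake_sample(0), fake_sample(0), "MSt", "Sw")
  }
  expect_equal(state$phase_seq, "MSt")
  update_feature_state(state, fake_sample(0), fake_sample(0), "TSt", "Sw")
  expect_equal(state$phase_seq, c("MSt", "TSt"))
})

test_that("spectral magnitudes satisfy DC, single-bin and Parseval identities", {
  x <- rep(3.2, 128)
  mags <- spectral_magnitudes(x)
  expect_length(mags, 65)
  expect_equal(mags[1], 128 * 3.2)
  expect_equal(max(mags[-1]), 0, tolerance = 1e-9)

  k <- 7
  x <- cos(2 * pi * k * (0:127) / 128)
  mags <- spectral_magnitudes(x)
  expect_equal(mags[k + 1], 64, tolerance = 1e-9)
  expect_lt(max(mags[-(k + 1)]), 1e-9)

  set.seed(13)
  x <- rnorm(128)
  full <- Mod(stats::fft(x))
  expect_equal(sum(full^2) / 128, sum(x^2), tolerance = 1e-9)
  expect_error(spectral_magnitudes(rnorm(64)), "128")
})

test_that("buffer features handle constants and pure tones", {
  f <- buffer_features(rep(2.5, 128))
  expect_equal(unname(f), c(2.5, 2.5, 0))

  # 2 Hz is not an exact bin at 50 Hz / 128 samples; nearest bin is 5
  x <- sin(2 * pi * 2 * (0:127) / 50)
  f <- buffer_features(x)
  expect_equal(unname(f["mean"]), 0, tolerance = 0.03)
  expect_equal(unname(f["rms"]), sqrt(0.5), tolerance = 0.03)
  expect_equal(unname(f["domfreq"]), 5 * 50 / 128)
})

test_that("buffer features match a brute-force DFT oracle on random buffers", {
  set.seed(17)
  n <- 128
  for (rep in 1:20) {
    x <- rnorm(n, sd = runif(1, 0.1, 3)) + runif(1, -2, 2)
    f <- buffer_features(x)
    expect_equal(unname(f["mean"]), sum(x) / n)
    expect_equal(unname(f["rms"]), sqrt(sum(x^2) / n))
    # direct O(n^2) DFT
    mags <- vapply(0:64, function(k) {
      Mod(sum(x * exp(-2i * pi * k * (0:(n - 1)) / n)))
    }, numeric(1))
    k <- which.max(mags[-1])
    expect_equal(unname(f["domfreq"]), k * 50 / n, tolerance = 1e-9)
  }
})

test_that("phase-sequence codes concatenate activations as decimal digits", {
  expect_equal(phase_sequence_code(c("MSt", "TSt", "PSw", "Sw")), 2345)
  expect_equal(phase_sequence_code(c("LR", "MSt", "TSt", "PSw")), 1234)
  expect_equal(phase_sequence_code(character(0)), 0)
  expect_equal(phase_sequence_code("Sw"), 5)
  expect_error(phase_sequence_code(rep("LR", 5)), "at most 4")
  expect_error(phase_sequence_code("XX"), "unknown")
})

test_that("phase codes stay in [0, 5555] with digits in 0..5", {
  set.seed(23)
  for (rep in 1:100) {
    phases <- sample(gait_phases(), sample(0:4, 1), replace = TRUE)
    code <- phase_sequence_code(phases)
    expect_gte(code, 0)
    expect_lte(code, 5555)
    digits <- as.integer(strsplit(sprintf("%04d", code), "")[[1]])
    expect_true(all(digits %in% 0:5))
  }
})

test_that("vectorized extraction equals the streaming computation on a replayed stream", {
  walk <- noiseless_walk(n_cycles = 4)
  norm <- normalize_stream(walk[c("time", "side", fsr_channels(),
                                  "accel_ap", "accel_v")], true_profile())
  phases <- lapply(c(left = "left", right = "right"), function(s) {
    active_phases(gpda_memberships(norm, s))
  })
  fast <- featurize_stream(norm, phases)

  left <- norm[norm$side == "left", ]
  right <- norm[norm$side == "right", ]
  state <- new_feature_state()
  slow <- list()
  for (i in seq_len(nrow(left))) {
    update_feature_state(state, left[i, ], right[i, ],
                         phases$left[i], phases$right[i])
    fv <- extract_feature_vector(state)
    if (!is.null(fv)) slow[[length(slow) + 1L]] <- fv
  }
  slow <- do.call(rbind, slow)
  expect_equal(unname(as.matrix(fast[feature_names()])), unname(slow),
               tolerance = 1e-9)
})

test_that("streaming state is a pure function of the last 128 samples", {
  set.seed(29)
  xs <- runif(200)
  run <- function(values) {
    state <- new_feature_state()
    for (v in values) {
      update_feature_state(state, fake_sample(v), fake_sample(v), "LR", "LR")
    }
    state$buffers
  }
  expect_equal(run(xs)[["left_fsr_heel"]],
               run(xs[73:200])[["left_fsr_heel"]])
})
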