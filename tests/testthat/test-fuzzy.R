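# Sigmoid memberships, rule inference, demarcation and the reference cycle.

test_that("membership sigmoid hits its landmarks", {
  for (s in c(5, 15, 50)) {
    expect_equal(membership_low(0.5, membership_params(s)), 0.5)
    expect_equal(membership_high(0.5, membership_params(s)), 0.5)
  }
  expect_equal(membership_low(0, membership_params(15)),
               1 / (1 + exp(-7.5)))
  expect_equal(membership_high(1, membership_params(15)),
               membership_low(0, membership_params(15)))
})

test_that("low and high grades are complementary and monotone", {
  x <- seq(0, 1, by = 0.01)
  for (s in c(15, 50)) {
    p <- membership_params(s)
    lo <- membership_low(x, p)
    expect_equal(lo + membership_high(x, p), rep(1, length(x)))
    expect_true(all(diff(lo) < 0))
    expect_true(all(lo > 0 & lo < 1))
  }
})

test_that("out-of-domain readings violate the normalization contract", {
  expect_error(membership_low(-0.01), "\\[0, 1\\]")
  expect_error(membership_low(1.01), "\\[0, 1\\]")
  expect_error(membership_params(slope = -1), "slope")
  expect_error(membership_params(inflection = 1), "inflection")
})

test_that("minimum T-norm reproduces the terminal-stance worked example", {
  rb <- default_rulebase()
  tst <- rb[rb$phase == "TSt", ]
  grade <- evaluate_rule(tst,
                         grade_low = c(fsr_heel = 0.95),
                         grade_high = c(fsr_5th = 0.90, fsr_1st = 1.00))
  expect_identical(grade, 0.90)
})

test_that("zero pressure everywhere activates swing and suppresses the rest", {
  pm <- infer_phase_memberships(c(fsr_heel = 0, fsr_5th = 0,
                                  fsr_1st = 0, fsr_toe = 0))
  expect_equal(pm$Sw, 1 / (1 + exp(-7.5)), tolerance = 1e-9)
  for (p in c("LR", "MSt", "TSt", "PSw")) {
    expect_lte(pm[[p]], 0.00056)
  }
})

test_that("don't-care channels cannot move a rule's grade", {
  base <- c(fsr_heel = 0.9, fsr_5th = 0.8, fsr_1st = 0.2, fsr_toe = 0.1)
  g0 <- infer_phase_memberships(base)$MSt
  for (v in c(0, 0.33, 0.77, 1)) {
    moved <- base
    moved["fsr_1st"] <- v
    moved["fsr_toe"] <- 1 - v
    expect_equal(infer_phase_memberships(moved)$MSt, g0)
  }
})

test_that("every phase grade respects the min T-norm bound and [0, 1]", {
  set.seed(21)
  rb <- default_rulebase()
  params <- default_membership_params()
  for (rep in 1:50) {
    x <- runif(4)
    names(x) <- fsr_channels()
    pm <- infer_phase_memberships(x)
    lo <- vapply(fsr_channels(),
                 function(ch) membership_low(x[[ch]], params[[ch]]),
                 numeric(1))
    hi <- 1 - lo
    for (i in seq_len(nrow(rb))) {
      grade <- pm[[rb$phase[i]]]
      expect_gte(grade, 0)
      expect_lte(grade, 1)
      for (ch in fsr_channels()) {
        lev <- rb[[ch]][i]
        if (is.na(lev)) next
        expect_lte(grade, (if (lev == "low") lo else hi)[[ch]] + 1e-12)
      }
    }
  }
})

test_that("ideal pressure patterns reach near-certain membership", {
  rb <- default_rulebase()
  for (i in seq_len(nrow(rb))) {
    x <- vapply(fsr_channels(), function(ch) {
      lev <- rb[[ch]][i]
      if (is.na(lev)) 0.5 else if (lev == "high") 1 else 0
    }, numeric(1))
    pm <- infer_phase_memberships(x)
    expect_gte(pm[[rb$phase[i]]], 0.999)
  }
})

test_that("a malformed rule base is rejected", {
  rb <- default_rulebase()
  rb[rb$phase == "MSt", fsr_channels()] <- NA
  expect_error(infer_phase_memberships(rep(0.5, 4), rulebase = rb),
               "antecedent")
  expect_error(infer_phase_memberships(rep(0.5, 4),
                                       rulebase = default_rulebase()[-1, ]),
               "one rule per")
})

test_that("a constant heel+fifth pattern demarcates one mid-stance event", {
  n <- 40
  pm <- infer_phase_memberships(
    data.frame(fsr_heel = rep(1, n), fsr_5th = 1, fsr_1st = 0.5,
               fsr_toe = 0.5),
    time = (seq_len(n) - 1) / 50)
  ev <- demarcate_phases(pm)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$phase, "MSt")
  expect_equal(ev$duration_ms, n * 20)
})

test_that("exact grade ties retain the previously active phase", {
  grades <- data.frame(time = (0:3) / 50,
                       LR = c(0.2, 0.9, 0.6, 0.2),
                       MSt = c(0.1, 0.1, 0.6, 0.6),
                       TSt = 0, PSw = 0, Sw = 0)
  class(grades) <- c("phase_memberships", "data.frame")
  expect_equal(active_phases(grades), c("LR", "LR", "LR", "MSt"))
})

test_that("noiseless walking demarcates phases in cyclic order", {
  walk <- noiseless_walk()
  norm <- normalize_stream(walk[c("time", "side", fsr_channels(),
                                  "accel_ap", "accel_v")], true_profile())
  ev <- demarcate_phases(gpda_memberships(norm, "left"))
  idx <- match(ev$phase, gait_phases())
  expect_true(all(diff(idx) %% 5 == 1))
})

test_that("reference durations follow the percentage arithmetic and sum to the cycle", {
  expect_equal(reference_phase_duration(10, 1000), 100)
  expect_equal(reference_phase_duration(40, 1200), 480)
  for (ct in c(600, 1000, 1234.5)) {
    expect_equal(sum(reference_cycle(ct)$duration_ms), ct)
  }
  expect_equal(sum(reference_schedule()), 100)
  expect_error(reference_phase_duration(-1, 1000), "phase_pct")
  expect_error(reference_phase_duration(10, 0), "positive")
})

test_that("phase-duration differences vanish when measurement equals reference", {
  ct <- 1000
  ref <- reference_cycle(ct)
  mk_cycle <- function(durations) {
    start <- cumsum(c(0, durations[-5])) / 1000
    data.frame(phase = gait_phases(), start = start,
               end = start + durations / 1000, duration_ms = durations)
  }
  ev <- do.call(rbind, lapply(0:2, function(k) {
    cyc <- mk_cycle(ref$duration_ms)
    cyc$start <- cyc$start + k
    cyc$end <- cyc$end + k
    cyc
  }))
  expect_equal(unname(phase_duration_differences(ev)), rep(0, 5))
})

test_that("a 110 ms loading response in a 1000 ms cycle is +10 ms over reference", {
  durations <- c(LR = 110, MSt = 200, TSt = 200, PSw = 90, Sw = 400)
  start <- cumsum(c(0, durations[-5])) / 1000
  one <- data.frame(phase = gait_phases(), start = start,
                    end = start + durations / 1000,
                    duration_ms = as.numeric(durations))
  ev <- rbind(one, transform(one, start = start + 1, end = end + 1))
  d <- phase_duration_differences(ev)
  expect_equal(unname(d["LR"]), 10)
  expect_equal(unname(d["PSw"]), -10)
})

test_that("duration differences agree with a brute-force per-cycle oracle", {
  set.seed(31)
  for (trial in 1:3) {
    n_cycles <- 4
    ev <- do.call(rbind, lapply(seq_len(n_cycles), function(k) {
      durations <- runif(5, 80, 500)
      start <- (k - 1) * 2 + cumsum(c(0, durations[-5])) / 1000
      data.frame(phase = gait_phases(), start = start,
                 end = start + durations / 1000, duration_ms = durations)
    }))
    # terminal LR onset so the final cycle is bounded
    ev <- rbind(ev, data.frame(phase = "LR", start = n_cycles * 2,
                               end = n_cycles * 2 + 0.1, duration_ms = 100))
    # oracle: explicit loop over cycles, spreadsheet-style
    sched <- c(10, 20, 20, 10, 40)
    acc <- matrix(0, n_cycles, 5)
    for (k in seq_len(n_cycles)) {
      cyc <- ev[((k - 1) * 5 + 1):(k * 5), ]
      for (j in 1:5) {
        acc[k, j] <- cyc$duration_ms[j] -
          sched[j] / 100 * sum(cyc$duration_ms)
      }
    }
    expect_equal(unname(phase_duration_differences(ev)), colMeans(acc),
                 tolerance = 1e-9)
  }
})

test_that("incomplete cycles are excluded with a warning", {
  durations <- c(100, 200, 200, 100, 400)
  start <- cumsum(c(0, durations[-5])) / 1000
  good <- data.frame(phase = gait_phases(), start = start,
                     end = start + durations / 1000,
                     duration_ms = durations)
  bad <- data.frame(phase = c("LR", "MSt", "Sw"),
                    start = 1 + c(0, 0.1, 0.3), end = 1 + c(0.1, 0.3, 1),
                    duration_ms = c(100, 200, 700))
  tail_lr <- data.frame(phase = "LR", start = 2, end = 2.1,
                        duration_ms = 100)
  ev <- rbind(good, bad, tail_lr)
  expect_warning(cycles <- segment_cycles(ev), "incomplete")
  expect_equal(length(cycles), 1L)
})
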