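test_that("class profiles encode the clinical gain signatures", {
  g <- function(label) {
    p <- class_profile(label)
    stats::setNames(p$gains$gain, p$gains$site)
  }
  for (label in c(malocclusion_classes(), habit_classes())) {
    p <- class_profile(label)
    expect_true(all(p$gains$gain >= 0))
    expect_gt(length(p$active_sites), 0)
    expect_identical(class_profile(label), p)  # deterministic
  }
  expect_true(all(g("AnI") == 1))
  an2 <- g("AnII")
  expect_lt(an2["MAN_LSM"], an2["MAX_LSM"])
  expect_lt(an2["MAN_RSM"], an2["MAX_RSM"])
  expect_lt(an2["MAX_LCI"], an2["MAN_LCI"])
  an3 <- g("AnIII")
  expect_lt(an3["MAX_LSM"], an3["MAN_LSM"])
  expect_lt(an3["MAN_LCI"], an3["MAX_LCI"])
  ob <- g("OB"); an1 <- g("AnI")
  expect_lt(ob["MAX_LCI"], an1["MAX_LCI"])
  expect_lt(ob["MAN_RCI"], an1["MAN_RCI"])
  expect_equal(ob["MAX_LSM"], an1["MAX_LSM"])  # molars unchanged
  md <- g("MD")
  left <- grep("_L", names(md), value = TRUE)
  expect_gt(max(abs(md[left] - md[occlusignal:::.mirror_site(left)])), 0)
  expect_error(class_profile("AnIV"), "valid labels")
})

test_that("pulse trains are biphasic, charge-balanced and correctly counted", {
  sh <- pulse_shape()
  expect_lt(sh$opening_amplitude, 0)
  v <- make_pulse_train(sh, rate = 1, fs = 50, duration = 10, seed = 1)
  expect_length(v, 500)
  expect_gt(max(v), 0)
  expect_lt(min(v), 0)
  # cycle count: one positive lobe per cycle, 10 +/- 1 cycles
  above <- v > 0.5 * max(v)
  n_cycles <- sum(diff(c(FALSE, above)) == 1)
  expect_true(abs(n_cycles - 10) <= 1)
  # per-cycle area ~ 0 (numeric integration of one isolated cycle)
  v0 <- make_pulse_train(sh, rate = 1, fs = 200, duration = 3,
                         jitter = 0, seed = 1)
  cycle <- v0[1:200]  # first full period holds exactly one cycle
  expect_lt(abs(sum(cycle) / 200) / (max(cycle) * 1), 0.05)
  expect_error(make_pulse_train(sh, rate = 20, fs = 50, duration = 10),
               "too high")
  expect_error(make_pulse_train(sh, rate = 1, fs = 50, duration = 0.5),
               "duration")
})

test_that("crosstalk matrices honour their invariants and are seeded", {
  m0 <- make_mixing(8, 0, seed = 42)
  expect_identical(m0$matrix, diag(8))
  m <- make_mixing(2, 0.3, seed = 1)
  expect_equal(diag(m$matrix), c(1, 1))
  off <- m$matrix[row(m$matrix) != col(m$matrix)]
  expect_true(all(abs(off) <= 0.3))
  expect_true(abs(det(m$matrix)) > 0)
  expect_identical(make_mixing(8, 0.2, seed = 7)$matrix,
                   make_mixing(8, 0.2, seed = 7)$matrix)
  expect_lt(kappa(make_mixing(16, 0.45, seed = 3)$matrix, exact = TRUE), 50)
})

test_that("clean recordings reduce to gain-scaled pulse trains", {
  rec <- simulate_recording("AnI", fs = 50, duration = 10, snr_db = Inf,
                            drift_amp = 0, crosstalk = 0, seed = 5)
  expect_identical(recording_channels(rec), tooth_sites("both")$site)
  peaks <- vapply(recording_channels(rec), function(ch) max(rec[[ch]]),
                  numeric(1))
  # every channel carries the same unit-gain pulse envelope
  expect_true(all(abs(peaks - max(peaks)) < 0.02))
  troughs <- vapply(recording_channels(rec), function(ch) min(rec[[ch]]),
                    numeric(1))
  expect_true(all(troughs < -0.3))
  expect_identical(
    as.matrix(rec[recording_channels(rec)]),
    as.matrix(simulate_recording("AnI", fs = 50, duration = 10,
                                 snr_db = Inf, drift_amp = 0, crosstalk = 0,
                                 seed = 5)[recording_channels(rec)])
  )
})

test_that("teeth grinding alternates posterior load between sides", {
  rec <- simulate_recording("GT", jaws = "mandible", duration = 16,
                            snr_db = Inf, drift_amp = 0, crosstalk = 0,
                            seed = 8)
  env <- function(ch) {
    x <- abs(rec[[ch]])
    # 2 s block energies
    tapply(x, rep(seq_len(8), each = 100), mean)
  }
  left <- env("MAN_LFM") + env("MAN_LSM")
  right <- env("MAN_RFM") + env("MAN_RSM")
  expect_lt(cor(left, right), 0)
})

test_that("lip biting silences molars relative to centric occlusion", {
  lb <- simulate_recording("LB", jaws = "mandible", duration = 10,
                           snr_db = Inf, drift_amp = 0, crosstalk = 0,
                           seed = 3)
  co <- simulate_recording("CO", jaws = "mandible", duration = 10,
                           snr_db = Inf, drift_amp = 0, crosstalk = 0,
                           seed = 3)
  ratio <- function(rec, molar) {
    r <- channel_rms(rec)
    r[molar] / mean(r[c("MAN_LCI", "MAN_RCI")])
  }
  molars <- c("MAN_LFM", "MAN_RFM", "MAN_LSM", "MAN_RSM")
  below <- vapply(molars, function(m) ratio(lb, m) < ratio(co, m),
                  logical(1))
  expect_gte(sum(below), 2)
})

test_that("datasets are balanced, deterministic and single-family", {
  recs <- simulate_dataset(10, malocclusion_classes(), duration = 2,
                           seed = 0)
  expect_length(recs, 50)
  labels <- vapply(recs, recording_label, character(1))
  expect_true(all(table(labels) == 10))
  recs2 <- simulate_dataset(10, malocclusion_classes(), duration = 2,
                            seed = 0)
  expect_identical(lapply(recs, as.data.frame), lapply(recs2, as.data.frame))
  expect_error(simulate_dataset(5, c("AnI", "GT")), "cannot be mixed")
  expect_error(simulate_dataset(5, c("AnI", "nope")), "unknown class")
})

test_that("drift puts energy below 1 Hz; clean pulse trains do not", {
  frac_below_1hz <- function(x, fs) {
    spec <- Mod(stats::fft(x))^2
    f <- pmin(0:(length(x) - 1), length(x) - 0:(length(x) - 1)) *
      fs / length(x)
    sum(spec[f < 1]) / sum(spec)
  }
  drifty <- simulate_recording("AnI", duration = 20, snr_db = Inf,
                               drift_amp = 0.5, crosstalk = 0, seed = 2)
  expect_gt(frac_below_1hz(drifty$MAX_LCI, 50), 0.01)
  # canonical periodic train: all power sits at >= 1 Hz harmonics (full
  # jitter trades a few percent of sub-1 Hz energy for train independence)
  clean <- make_pulse_train(pulse_shape(), rate = 1, fs = 50,
                            duration = 20, jitter = 0, seed = 2)
  expect_lt(frac_below_1hz(clean, 50), 0.001)
})

test_that("class signatures survive default noise in nearly all recordings", {
  hits <- vapply(seq_len(200), function(s) {
    rec <- simulate_recording("AnII", duration = 10, seed = s)
    r <- channel_rms(rec)
    (r["MAN_LSM"] + r["MAN_RSM"]) < (r["MAX_LSM"] + r["MAX_RSM"])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
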