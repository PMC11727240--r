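test_that("low-pass filter passes the passband and kills the stopband", {
  fs <- 200
  t <- (0:(fs * 5 - 1)) / fs
  dc <- lowpass_filter(one_channel(rep(3, length(t)), fs), 20)
  expect_lt(max(abs(dc$MAX_LCI - 3)), 1e-6)
  expect_equal(nrow(dc), length(t))
  expect_equal(recording_fs(dc), fs)
  hi <- lowpass_filter(one_channel(sin(2 * pi * 40 * t), fs), 20)
  expect_lt(rms(hi$MAX_LCI) / rms(sin(2 * pi * 40 * t)), 0.01)
  lo <- lowpass_filter(one_channel(sin(2 * pi * 2 * t), fs), 20)
  expect_lt(abs(rms(lo$MAX_LCI) / rms(sin(2 * pi * 2 * t)) - 1), 0.01)
  expect_error(lowpass_filter(one_channel(t, 30), 20), "Nyquist")
})

test_that("drift removal zeroes the sub-1 Hz band exactly", {
  fs <- 50
  t <- (0:(fs * 60 - 1)) / fs
  drift <- sin(2 * pi * 0.3 * t)
  out <- remove_baseline_drift(one_channel(drift, fs))
  # Parseval oracle: residual energy = energy in the kept bins
  spec <- stats::fft(drift)
  f <- pmin(0:(length(t) - 1), length(t) - 0:(length(t) - 1)) * fs / length(t)
  expected_residual <- sum(Mod(spec[f >= 1])^2) / length(t)
  expect_lt(sum(out$MAX_LCI^2) / sum(drift^2), 0.01)
  expect_equal(sum(out$MAX_LCI^2), expected_residual, tolerance = 1e-6)
  # constant input is removed entirely (DC bin)
  const <- remove_baseline_drift(one_channel(rep(2.5, 200), fs))
  expect_lt(max(abs(const$MAX_LCI)), 1e-12)
  expect_error(remove_baseline_drift(one_channel(rep(1, 50), fs)),
               "too short")
})

test_that("drift removal is idempotent, mean-free and never adds energy", {
  withr::with_seed(4, {
    for (i in 1:5) {
      fs <- 50
      x <- rnorm(500) + sin(2 * pi * 0.4 * (0:499) / fs) + i
      rec <- one_channel(x, fs)
      once <- remove_baseline_drift(rec)
      twice <- remove_baseline_drift(once)
      expect_lt(max(abs(once$MAX_LCI - twice$MAX_LCI)),
                1e-9 * max(abs(once$MAX_LCI)))
      expect_lt(abs(mean(once$MAX_LCI)), 1e-9 * rms(once$MAX_LCI))
      expect_lte(sum(once$MAX_LCI^2), sum(x^2))
    }
  })
})

test_that("drift-contaminated pulse trains are restored", {
  fs <- 50
  clean <- make_pulse_train(pulse_shape(), rate = 1, fs = fs,
                            duration = 60, jitter = 0, seed = 11)
  t <- (0:(length(clean) - 1)) / fs
  noisy <- clean + 0.5 * sin(2 * pi * 0.3 * t + 1)
  out <- remove_baseline_drift(one_channel(noisy, fs))
  expect_gt(cor(out$MAX_LCI, clean), 0.99)
})

test_that("the Amari index is zero exactly on scaled permutations", {
  expect_equal(amari_index(diag(4)), 0)
  perm <- diag(4)[c(3, 1, 4, 2), ] %*% diag(c(2, -1, 0.5, 10))
  expect_equal(amari_index(perm), 0)
  expect_equal(amari_index(matrix(1, 2, 2)), 1)
  expect_gt(amari_index(matrix(c(1, .5, .5, 1), 2)), 0)
  expect_error(amari_index(matrix(1, 2, 3)), "square")
  expect_error(amari_index(rbind(c(1, 1), c(0, 0))), "all-zero")
})

test_that("FastICA recovers known mixings of super-Gaussian sources", {
  # identity mixing of independent unit-variance Laplacian sources:
  # nothing to unmix
  withr::with_seed(42, {
    s <- matrix(sample(c(-1, 1), 2 * 8000, TRUE) * rexp(2 * 8000),
                2, 8000) / sqrt(2)
    rec <- new_recording(t(s), fs = 50,
                         channels = c("MAX_LCI", "MAX_RCI"))
    um <- fastica_unmix(rec, seed = 1)
    expect_lt(amari_index(um$unmixing), 0.05)
    expect_true(um$converged)
    # sources match inputs up to permutation/sign
    cm <- abs(cor(t(um$sources), t(s)))
    expect_true(all(apply(cm, 1, max) > 0.99))
    # unit variance and orthonormal rotation rows
    expect_equal(unname(apply(um$sources, 1, var)), c(1, 1),
                 tolerance = 1e-2)
    expect_lt(max(abs(tcrossprod(um$rotation) - diag(2))), 1e-6)
    # known 2x2 mixing
    a <- matrix(c(1, 0.4, 0.3, 1), 2)
    recm <- new_recording(t(a %*% s), fs = 50,
                          channels = c("MAX_LCI", "MAX_RCI"))
    umm <- fastica_unmix(recm, seed = 1)
    expect_lt(amari_index(umm$unmixing %*% a), 0.05)
  })
})

test_that("FastICA rejects rank-deficient input", {
  x <- matrix(rnorm(300), ncol = 3)
  x[, 3] <- x[, 1] * 2                      # collinear channel
  rec <- new_recording(x, fs = 50,
                       channels = c("MAX_LCI", "MAX_RCI", "MAX_LFP"))
  expect_error(fastica_unmix(rec, seed = 1), "rank-deficient")
})

test_that("sources re-align to reference channels by correlation", {
  withr::with_seed(9, {
    x <- matrix(rnorm(4 * 400), 4, 400)
    chans <- c("MAN_LCI", "MAN_RCI", "MAN_LFP", "MAN_RFP")
    ref <- new_recording(t(x), fs = 50, channels = chans)
    perm <- c(3, 1, 4, 2)
    flip <- c(1, -1, -1, 1)
    fake <- structure(
      list(sources = diag(flip) %*% x[perm, ]),
      class = "occl_unmix"
    )
    aligned <- align_sources(fake, ref, rescale = FALSE)
    expect_equal(as.matrix(aligned[chans]), t(x), ignore_attr = TRUE,
                 tolerance = 1e-12)
    # with noise: same assignment as the brute-force best over all 4!
    noisy <- structure(
      list(sources = diag(flip) %*% x[perm, ] + rnorm(1600, sd = 0.05)),
      class = "occl_unmix"
    )
    aligned2 <- align_sources(noisy, ref, rescale = FALSE)
    perms <- rbind(
      c(1,2,3,4),c(1,2,4,3),c(1,3,2,4),c(1,3,4,2),c(1,4,2,3),c(1,4,3,2),
      c(2,1,3,4),c(2,1,4,3),c(2,3,1,4),c(2,3,4,1),c(2,4,1,3),c(2,4,3,1),
      c(3,1,2,4),c(3,1,4,2),c(3,2,1,4),c(3,2,4,1),c(3,4,1,2),c(3,4,2,1),
      c(4,1,2,3),c(4,1,3,2),c(4,2,1,3),c(4,2,3,1),c(4,3,1,2),c(4,3,2,1))
    cm <- abs(cor(t(noisy$sources), t(x)))
    scores <- apply(perms, 1, function(p) sum(cm[cbind(seq_len(4), p)]))
    best <- perms[which.max(scores), ]
    got <- vapply(chans, function(ch) {
      which.max(abs(cor(aligned2[[ch]], t(noisy$sources))))
    }, integer(1))
    expect_equal(unname(got[best]), 1:4)
  })
  zero_ref <- new_recording(matrix(0, 100, 2), fs = 50,
                            channels = c("MAX_LCI", "MAX_RCI"))
  fake <- structure(list(sources = matrix(rnorm(200), 2, 100)),
                    class = "occl_unmix")
  expect_error(align_sources(fake, zero_ref), "cannot be aligned")
})

test_that("alignment restores the amplitude scale of each site", {
  rec <- simulate_recording("AnII", duration = 20, snr_db = 25,
                            drift_amp = 0, seed = 21)
  um <- fastica_unmix(rec, seed = 1)
  aligned <- align_sources(um, rec)
  r_in <- channel_rms(rec)
  r_out <- channel_rms(aligned)
  expect_gt(cor(r_in, r_out), 0.9)
})

test_that("conditioning preserves sample count and sampling rate", {
  rec <- simulate_recording("OB", duration = 8, seed = 13)
  cond <- condition_recording(rec, seed = 2)
  expect_equal(nrow(cond), nrow(rec))
  expect_equal(recording_fs(cond), recording_fs(rec))
  expect_identical(recording_channels(cond), recording_channels(rec))
  expect_identical(recording_label(cond), "OB")
})
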