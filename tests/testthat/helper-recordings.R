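# shared fixture builders (everything is generated in code at test time)

# single-channel recording from a plain vector
one_channel <- function(v, fs, channel = "MAX_LCI", label = NA_character_) {
  new_recording(matrix(v, ncol = 1), fs = fs, channels = channel,
                label = label)
}

rms <- function(x) sqrt(mean(x^2))

# per-channel RMS of a recording, named by site
channel_rms <- function(rec) {
  vapply(recording_channels(rec), function(ch) rms(rec[[ch]]), numeric(1))
}

# three well-separated Gaussian blobs in 10-D, 20 points each (fixed seed,
# used by the t-SNE checks)
make_blobs <- function(seed = 123, n_per = 20, d = 10, spread = 10) {
  withr::with_seed(seed, {
    centers <- matrix(rnorm(3 * d, sd = spread), 3, d)
    x <- do.call(rbind, lapply(1:3, function(k) {
      matrix(rnorm(n_per * d), n_per, d) +
        matrix(centers[k, ], n_per, d, byrow = TRUE)
    }))
    list(x = x, labels = rep(c("a", "b", "c"), each = n_per))
  })
}

# small labelled feature table with informative columns (for split /
# suite tests that do not need the simulator)
toy_feature_table <- function(n_per_class = 12, classes = c("A", "B", "C"),
                              seed = 1, noise = 0.3) {
  withr::with_seed(seed, {
    rows <- lapply(seq_along(classes), function(k) {
      tibble::tibble(
        recording_id = sprintf("%s_%02d", classes[k], seq_len(n_per_class)),
        label = classes[k],
        f1 = k + rnorm(n_per_class, sd = noise),
        f2 = -k + rnorm(n_per_class, sd = noise),
        f3 = rnorm(n_per_class)
      )
    })
    dplyr::bind_rows(rows)
  })
}
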