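# Synthetic recording generator: per-site biphasic pulse trains scaled by
# the class profile, mixed through an inter-channel crosstalk matrix, with
# sub-1 Hz baseline drift and additive white Gaussian noise.

#' Inter-channel crosstalk matrix
#'
#' Models capacitive/resistive leakage between sensor channels as a square
#' mixing matrix with unit diagonal and random off-diagonal entries drawn
#' uniformly from `[-crosstalk_level, crosstalk_level]`. Matrices with
#' condition number >= 50 are redrawn (bounded retries), so the mixing is
#' always comfortably invertible and ICA-recoverable.
#'
#' @param n_channels Number of channels, >= 2.
#' @param crosstalk_level Off-diagonal magnitude bound in `[0, 1)`.
#' @param seed Integer seed; the same seed always yields the same matrix.
#' @param max_tries Redraw budget before giving up.
#'
#' @return A list of class `occl_mixing` with `matrix` and
#'   `crosstalk_level`.
#' @export
make_mixing <- function(n_channels, crosstalk_level, seed, max_tries = 25) {
  stopifnot(n_channels >= 2, crosstalk_level >= 0, crosstalk_level < 1)
  if (crosstalk_level == 0) {
    m <- diag(n_channels)
  } else {
    draws <- withr::with_seed(
      as.integer(seed),
      replicate(max_tries,
                matrix(runif(n_channels^2, -crosstalk_level, crosstalk_level),
                       n_channels),
                simplify = FALSE)
    )
    m <- NULL
    for (d in draws) {
      cand <- d
      diag(cand) <- 1
      if (kappa(cand, exact = TRUE) < 50) {
        m <- cand
        break
      }
    }
    if (is.null(m)) {
      stop("could not draw a crosstalk matrix with condition number < 50 in ",
           max_tries, " tries at level ", crosstalk_level, call. = FALSE)
    }
  }
  structure(list(matrix = m, crosstalk_level = crosstalk_level),
            class = "occl_mixing")
}

#' Simulate one labeled multichannel recording
#'
#' Each active site receives an independent jittered pulse train scaled by
#' the class-profile gain; teeth-grinding (GT) recordings additionally gate
#' posterior sites with complementary 2 s left/right blocks. Observed
#' channels are `mixing %*% clean` plus a slow sinusoidal baseline drift
#' (random phase per channel) and white Gaussian noise at the requested
#' signal-to-noise ratio. The clean (pre-mixing, noise-free) signal is a
#' deterministic function of `seed` alone, so ground truth can be
#' regenerated by calling again with `snr_db = Inf`, `drift_amp = 0` and
#' identity mixing.
#'
#' @param label Class label, see [malocclusion_classes()]/[habit_classes()].
#' @param jaws `"both"` (16 channels), `"maxilla"` or `"mandible"` (8).
#' @param fs Sampling rate, Hz (default 50, the device ceiling).
#' @param duration Recording length in seconds.
#' @param snr_db Signal-to-noise ratio in dB (`Inf` disables noise). The
#'   noise sd is set against the mean mixed-clean channel power, so silent
#'   channels still carry sensor noise.
#' @param drift_amp Baseline drift amplitude in volts (0 disables).
#' @param drift_freq Drift frequency, must be < 1 Hz (the conditioning
#'   stage only removes sub-1 Hz components).
#' @param drift_ramp Optional linear ramp reaching this many volts at the
#'   end of the recording (default 0).
#' @param mixing An [make_mixing()] spec, or `NULL` to draw one at
#'   `crosstalk` level from a sub-seed of `seed`.
#' @param crosstalk Crosstalk level used when `mixing` is `NULL`
#'   (default 0.15).
#' @param pulse Pulse shape, see [pulse_shape()].
#' @param pulse_jitter Per-cycle timing jitter fraction (default 1: fully
#'   desynchronised, mutually uncorrelated site pulse trains).
#' @param gt_block_s Left/right alternation block length for GT, seconds.
#' @param seed Integer seed; identical calls are bit-identical.
#' @param subject_id Identifier stored with the recording.
#'
#' @return An `occl_recording` tibble (see [new_recording()]).
#' @export
simulate_recording <- function(label, jaws = c("both", "maxilla", "mandible"),
                               fs = 50, duration = 10, snr_db = 20,
                               drift_amp = 0.5, drift_freq = 0.3,
                               drift_ramp = 0, mixing = NULL, crosstalk = 0.15,
                               pulse = pulse_shape(), pulse_jitter = 1,
                               gt_block_s = 2, seed = 1,
                               subject_id = NA_character_) {
  jaws <- match.arg(jaws)
  .check_label(label)
  if (drift_freq >= 1) {
    stop("`drift_freq` must be < 1 Hz so the drift filter can remove it",
         call. = FALSE)
  }
  profile <- class_profile(label)
  sites <- tooth_sites(jaws)
  channels <- sites$site
  n_ch <- length(channels)
  n <- round(fs * duration)
  t <- (seq_len(n) - 1) / fs

  sub <- .derive_seeds(seed, n_ch + 2)
  gains <- profile$gains$gain[match(channels, profile$gains$site)]
  # mirrored mandibular-deviation variant: odd seeds swap left/right
  if (label == "MD" && as.integer(seed) %% 2L == 1L) {
    gains <- gains[match(.mirror_site(channels), channels)]
  }

  clean <- matrix(0, n_ch, n)
  for (i in seq_len(n_ch)) {
    if (gains[i] == 0) next
    clean[i, ] <- gains[i] *
      make_pulse_train(pulse, rate = profile$pulse_rate, fs = fs,
                       duration = duration, jitter = pulse_jitter,
                       seed = sub[i])
  }
  if (profile$alternation == "left_right") {
    posterior <- sites$tooth_type %in% c("premolar", "first_molar", "second_molar")
    left_on <- (floor(t / gt_block_s) %% 2) == 0
    for (i in which(posterior)) {
      mask <- if (sites$side[i] == "left") left_on else !left_on
      clean[i, ] <- clean[i, ] * mask
    }
  }

  if (is.null(mixing)) {
    mixing <- if (crosstalk > 0) {
      make_mixing(n_ch, crosstalk, seed = sub[n_ch + 1])
    } else {
      structure(list(matrix = diag(n_ch), crosstalk_level = 0),
                class = "occl_mixing")
    }
  }
  stopifnot(inherits(mixing, "occl_mixing"))
  if (nrow(mixing$matrix) != n_ch) {
    stop("mixing matrix dimension (", nrow(mixing$matrix),
         ") does not match channel count (", n_ch, ")", call. = FALSE)
  }
  observed <- mixing$matrix %*% clean

  extras <- withr::with_seed(sub[n_ch + 2], {
    phases <- runif(n_ch, 0, 2 * pi)
    noise_raw <- matrix(rnorm(n_ch * n), n_ch, n)
    list(phases = phases, noise = noise_raw)
  })
  if (drift_amp > 0 || drift_ramp != 0) {
    drift <- drift_amp *
      sin(outer(extras$phases, 2 * pi * drift_freq * t, `+`)) +
      matrix(drift_ramp * t / max(t[n], 1e-12), n_ch, n, byrow = TRUE)
    observed <- observed + drift
  }
  if (is.finite(snr_db)) {
    p_signal <- mean(rowMeans((mixing$matrix %*% clean)^2))
    sigma <- sqrt(max(p_signal, 1e-24) / 10^(snr_db / 10))
    observed <- observed + sigma * extras$noise
  }

  new_recording(t(observed), fs = fs, channels = channels, label = label,
                seed = seed, subject_id = subject_id)
}

#' Simulate a balanced labeled dataset
#'
#' @param n_per_class Recordings per class, >= 1.
#' @param classes Labels drawn from one task family only (all
#'   malocclusions or all habits); mixing the families is rejected.
#' @param seed Master seed; per-recording seeds are derived from it.
#' @param ... Further arguments passed to [simulate_recording()].
#'
#' @return A list of `n_per_class * length(classes)` recordings, grouped by
#'   class, each with a `subject_id` of the form `sim_<label>_<k>`.
#' @export
#' @examples
#' recs <- simulate_dataset(2, c("AnI", "AnII"), duration = 4, seed = 1)
simulate_dataset <- function(n_per_class, classes, seed = 1, ...) {
  stopifnot(n_per_class >= 1, length(classes) >= 1)
  classes <- unique(as.character(classes))
  in_mal <- classes %in% malocclusion_classes()
  in_hab <- classes %in% habit_classes()
  if (any(!(in_mal | in_hab))) {
    stop("unknown class label(s): ",
         paste(classes[!(in_mal | in_hab)], collapse = ", "), call. = FALSE)
  }
  if (any(in_mal) && any(in_hab)) {
    stop("malocclusion and habit labels cannot be mixed in one dataset",
         call. = FALSE)
  }
  total <- n_per_class * length(classes)
  sub <- .derive_seeds(seed, total)
  idx <- 0
  recs <- vector("list", total)
  for (cl in classes) {
    for (k in seq_len(n_per_class)) {
      idx <- idx + 1
      recs[[idx]] <- simulate_recording(
        cl, seed = sub[idx],
        subject_id = sprintf("sim_%s_%03d", cl, k), ...
      )
    }
  }
  recs
}
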