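# Raw-signal conditioning: (1) zero-phase low-pass noise reduction,
# (2) Fourier removal of sub-1 Hz baseline drift, (3) FastICA separation of
# crosstalk-mixed channels (fastica.R). Steps are applied in that order and
# each preserves sample count and sampling rate.

# --- zero-phase IIR filtering ------------------------------------------------

# single-pass IIR filtering started from the steady state of a constant
# input equal to the first sample, so a DC signal passes with no start-up
# transient
.filter_ss <- function(b, a, x) {
  h1 <- sum(b) / sum(a)
  as.numeric(signal::filter(b, a, x,
                            init.x = rep(x[1], length(b) - 1),
                            init.y = rep(h1 * x[1], length(a) - 1)))
}

# extend a series by `pad` samples of linear prediction (Burg AR fit): a
# smooth continuation that keeps oscillatory signals oscillating, so the
# pad junction injects almost no spurious passband energy. Falls back to a
# mirror extension when the AR fit is unavailable (near-constant input).
.ar_extend <- function(x, pad) {
  n <- length(x)
  fit <- tryCatch(
    stats::ar(x, aic = FALSE, order.max = min(12, floor(n / 3)),
              method = "burg", demean = TRUE),
    error = function(e) NULL
  )
  if (is.null(fit) || length(fit$ar) == 0) {
    # near-degenerate input: even mirror extension
    return(c(rev(x[2:(pad + 1)]), x, x[(n - 1):(n - pad)]))
  }
  p <- length(fit$ar)
  predict_on <- function(v) {
    out <- numeric(pad)
    hist <- v[n:(n - p + 1)] - fit$x.mean
    for (k in seq_len(pad)) {
      nxt <- sum(fit$ar * hist)
      out[k] <- nxt + fit$x.mean
      hist <- c(nxt, hist[-p])
    }
    out
  }
  c(rev(predict_on(rev(x))), x, predict_on(x))
}

# forward-backward filtering with linear-prediction edge extension and
# steady-state initial conditions (no group delay, minimal edge transients)
.filtfilt_padded <- function(b, a, x) {
  # pad until the slowest pole has decayed below 1e-6
  pmax_mod <- max(Mod(polyroot(rev(a))), 0.5)
  pad <- ceiling(log(1e-6) / log(min(pmax_mod, 0.999)))
  pad <- min(length(x) - 1, max(pad, 3 * (max(length(a), length(b)) - 1)))
  n <- length(x)
  xe <- .ar_extend(x, pad)
  fwd <- rev(.filter_ss(b, a, xe))
  back <- rev(.filter_ss(b, a, fwd))
  back[(pad + 1):(pad + n)]
}

#' Low-pass noise filter
#'
#' Emulates the acquisition front end's 20 Hz anti-noise filter in
#' software: an order-8 type-II Chebyshev low-pass (40 dB stopband from
#' 1.25 x cutoff, monotone passband) applied forward and backward per
#' channel, so the response is zero-phase and the effective attenuation is
#' doubled.
#'
#' @param rec An `occl_recording`.
#' @param cutoff Cutoff frequency in Hz; must be below the Nyquist
#'   frequency `fs/2`.
#' @param order Half-filter order (per pass).
#' @return The filtered recording (same length, fs and metadata).
#' @export
lowpass_filter <- function(rec, cutoff = 20, order = 8) {
  stopifnot(inherits(rec, "occl_recording"))
  fs <- recording_fs(rec)
  if (cutoff >= fs / 2) {
    stop("low-pass cutoff (", cutoff, " Hz) must be below the Nyquist ",
         "frequency fs/2 = ", fs / 2, " Hz", call. = FALSE)
  }
  nyq <- fs / 2
  if (1.25 * cutoff < 0.95 * nyq) {
    # second argument is the stopband attenuation in dB for a type-II design
    filt <- signal::cheby2(order, 40, 1.25 * cutoff / nyq, type = "low")
  } else {
    # stopband edge not representable at this fs: fall back to a
    # maximally-flat design at the cutoff itself
    filt <- signal::butter(order, cutoff / nyq, type = "low")
  }
  x <- .rec_matrix(rec)
  y <- t(apply(x, 1, function(ch) .filtfilt_padded(filt$b, filt$a, ch)))
  .rec_update(rec, y)
}

# --- Fourier baseline-drift removal -----------------------------------------

#' Remove sub-1 Hz baseline drift
#'
#' Per channel: take the discrete Fourier transform, zero every bin with
#' `|f| < drift_cutoff` (DC included; a bin at exactly the cutoff is kept),
#' and invert. This removes the slow baseline wander caused by charge
#' accumulation while leaving the pulse band untouched. The operation is
#' idempotent and never increases signal energy.
#'
#' @param rec An `occl_recording` of length at least `2 / drift_cutoff`
#'   seconds (so the removable band spans at least two DFT bins).
#' @param drift_cutoff Drift band edge in Hz (default 1).
#' @return The drift-free recording; each channel has zero mean.
#' @export
remove_baseline_drift <- function(rec, drift_cutoff = 1) {
  stopifnot(inherits(rec, "occl_recording"), drift_cutoff > 0)
  fs <- recording_fs(rec)
  n <- nrow(rec)
  if (n / fs < 2 / drift_cutoff) {
    stop("recording too short for drift removal: need at least ",
         2 / drift_cutoff, " s (frequency resolution coarser than the ",
         drift_cutoff, " Hz cutoff)", call. = FALSE)
  }
  k <- 0:(n - 1)
  freq <- pmin(k, n - k) * fs / n
  kill <- freq < drift_cutoff * (1 - 1e-12)
  x <- .rec_matrix(rec)
  y <- t(apply(x, 1, function(ch) {
    spec <- fft(ch)
    spec[kill] <- 0
    Re(fft(spec, inverse = TRUE)) / n
  }))
  .rec_update(rec, y)
}

#' Full conditioning chain
#'
#' Applies, in order: low-pass filtering, baseline-drift removal and
#' (optionally) FastICA unmixing with correlation-based re-alignment to the
#' pre-ICA channels.
#'
#' @param rec An `occl_recording`.
#' @param lowpass Low-pass cutoff in Hz (`NA` to skip).
#' @param drift_cutoff Drift band edge in Hz (`NA` to skip).
#' @param ica Logical: run FastICA + [align_sources()]?
#' @param seed Seed for the ICA initialisation.
#' @param ... Passed to [fastica_unmix()].
#' @return The conditioned recording.
#' @export
condition_recording <- function(rec, lowpass = 20, drift_cutoff = 1,
                                ica = TRUE, seed = 1, ...) {
  if (!is.na(lowpass)) rec <- lowpass_filter(rec, lowpass)
  if (!is.na(drift_cutoff)) rec <- remove_baseline_drift(rec, drift_cutoff)
  if (isTRUE(ica)) {
    unmix <- fastica_unmix(rec, seed = seed, ...)
    rec <- align_sources(unmix, rec)
  }
  rec
}
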