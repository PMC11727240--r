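# Biphasic contact-separation pulse model. One bite cycle produces a
# positive half-sine lobe while the tooth closes onto the sensor and a
# negative half-sine lobe while it separates; the lobe areas cancel so a
# full cycle transfers no net charge.

#' Describe a biphasic contact-separation pulse
#'
#' Defaults give a 0.15 s closing lobe of +1 V and a 0.25 s opening lobe
#' whose amplitude is set so the two half-sine areas cancel
#' (`opening_amplitude = -closing_amplitude * closing_duration /
#' opening_duration`).
#'
#' @param closing_amplitude Peak voltage of the closing (positive) lobe, > 0.
#' @param closing_duration,opening_duration Lobe durations in seconds, > 0.
#' @param opening_amplitude Trough voltage of the opening lobe, < 0.
#'
#' @return A list of class `occl_pulse_shape`.
#' @export
pulse_shape <- function(closing_amplitude = 1, closing_duration = 0.15,
                        opening_duration = 0.25,
                        opening_amplitude = -closing_amplitude *
                          closing_duration / opening_duration) {
  stopifnot(closing_amplitude > 0, opening_amplitude < 0,
            closing_duration > 0, opening_duration > 0)
  structure(
    list(closing_amplitude = closing_amplitude,
         opening_amplitude = opening_amplitude,
         closing_duration = closing_duration,
         opening_duration = opening_duration),
    class = "occl_pulse_shape"
  )
}

# add one biphasic cycle starting at t0 (seconds) into waveform v in place;
# only the cycle's own samples are touched, so long trains stay cheap
.add_pulse_cycle <- function(v, fs, t0, shape, amp = 1) {
  active <- shape$closing_duration + shape$opening_duration
  i0 <- max(floor(t0 * fs) + 1, 1)
  i1 <- min(ceiling((t0 + active) * fs) + 1, length(v))
  if (i1 < i0) return(v)
  idx <- i0:i1
  tc <- (idx - 1) / fs - t0
  seg <- numeric(length(idx))
  inc <- tc >= 0 & tc < shape$closing_duration
  seg[inc] <- shape$closing_amplitude * sin(pi * tc[inc] / shape$closing_duration)
  top <- tc >= shape$closing_duration & tc < active
  seg[top] <- shape$opening_amplitude *
    sin(pi * (tc[top] - shape$closing_duration) / shape$opening_duration)
  v[idx] <- v[idx] + amp * seg
  v
}

#' Generate a train of biphasic pulses
#'
#' One cycle is laid down per period of the nominal rate; `jitter` shifts
#' each cycle start independently and uniformly within `jitter` x one full
#' period. At `jitter = 1` the relative lag between any two trains is
#' uniform over the period and redrawn every cycle, so trains generated
#' from different seeds are empirically uncorrelated (a biphasic cycle has
#' near-zero area) — which is what lets ICA treat per-site trains as
#' independent sparse sources. A heavily jittered cycle may occasionally
#' spill into the next period and overlap its successor.
#'
#' @param shape A [pulse_shape()].
#' @param rate Nominal cycles per second; must satisfy `rate <= fs / 4` so a
#'   biphasic cycle is resolvable.
#' @param fs Sampling rate, Hz.
#' @param duration Train length in seconds, > `1/rate`.
#' @param jitter Timing jitter in `[0, 1]` (fraction of one period each
#'   cycle start may shift by; 1 = fully desynchronised trains).
#' @param seed Integer seed for the jitter draws.
#'
#' @return Numeric vector of `round(fs * duration)` voltage samples.
#' @export
#' @examples
#' v <- make_pulse_train(pulse_shape(), rate = 1, fs = 50, duration = 10, seed = 1)
make_pulse_train <- function(shape = pulse_shape(), rate, fs, duration,
                             jitter = 0, seed = 1) {
  stopifnot(inherits(shape, "occl_pulse_shape"), rate > 0, fs > 0,
            jitter >= 0, jitter <= 1)
  if (rate > fs / 4) {
    stop("pulse rate ", rate, " Hz too high for fs = ", fs,
         " Hz (need rate <= fs/4)", call. = FALSE)
  }
  if (duration <= 1 / rate) {
    stop("`duration` must exceed one pulse period (1/rate)", call. = FALSE)
  }
  n <- round(fs * duration)
  period <- 1 / rate
  active <- shape$closing_duration + shape$opening_duration
  n_cycles <- floor(duration * rate)
  offsets <- withr::with_seed(as.integer(seed),
                              runif(n_cycles, 0, 1) * jitter * period)
  v <- numeric(n)
  for (k in seq_len(n_cycles)) {
    t0 <- (k - 1) * period + offsets[k]
    if (t0 + active > duration) next
    v <- .add_pulse_cycle(v, fs, t0, shape)
  }
  v
}
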