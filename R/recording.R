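# A recording is a tibble: one `t_s` column plus one voltage column per
# tooth-site channel, with sampling metadata kept in attributes so the whole
# object still behaves as an ordinary data frame in dplyr chains.

#' Construct a recording tibble
#'
#' @param samples Numeric matrix or data frame, channels in columns
#'   (canonical site order), one row per sample, volts.
#' @param fs Sampling rate in Hz (> 0).
#' @param channels Character vector of channel (tooth-site) names matching
#'   the columns of `samples`.
#' @param label Occlusion class label, or `NA` for unlabeled data.
#' @param seed Integer seed the recording was generated from, or `NA`.
#' @param subject_id Free-text subject/model identifier.
#'
#' @return A tibble of class `occl_recording` with column `t_s` (seconds)
#'   followed by the channel columns; `fs`, `label`, `seed` and
#'   `subject_id` are attached as attributes (see [recording_meta()]).
#' @export
new_recording <- function(samples, fs, channels = colnames(samples),
                          label = NA_character_, seed = NA_integer_,
                          subject_id = NA_character_) {
  samples <- as.matrix(samples)
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  }
  if (is.null(channels)) stop("channel names are required", call. = FALSE)
  if (anyDuplicated(channels)) stop("channel names must be unique", call. = FALSE)
  if (length(channels) != ncol(samples)) {
    stop("`channels` length does not match the number of sample columns",
         call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("all sample values must be finite", call. = FALSE)
  }
  out <- tibble::as_tibble(as.data.frame(samples))
  names(out) <- channels
  out <- dplyr::bind_cols(
    tibble::tibble(t_s = (seq_len(nrow(samples)) - 1) / fs), out
  )
  attr(out, "fs") <- fs
  attr(out, "label") <- as.character(label)
  attr(out, "seed") <- if (is.na(seed)) NA_integer_ else as.integer(seed)
  attr(out, "subject_id") <- as.character(subject_id)
  class(out) <- c("occl_recording", class(out))
  out
}

#' Recording metadata
#'
#' @param rec A recording tibble.
#' @return A list with `fs`, `label`, `seed`, `subject_id`, `channels`,
#'   `n_channels` and `duration_s`.
#' @export
recording_meta <- function(rec) {
  list(
    fs = attr(rec, "fs"),
    label = attr(rec, "label"),
    seed = attr(rec, "seed"),
    subject_id = attr(rec, "subject_id"),
    channels = recording_channels(rec),
    n_channels = length(recording_channels(rec)),
    duration_s = nrow(rec) / attr(rec, "fs")
  )
}

#' @rdname recording_meta
#' @export
recording_channels <- function(rec) setdiff(names(rec), "t_s")

#' @rdname recording_meta
#' @export
recording_fs <- function(rec) attr(rec, "fs")

#' @rdname recording_meta
#' @export
recording_label <- function(rec) attr(rec, "label")

# channels x time matrix view used by the numeric stages
.rec_matrix <- function(rec) t(as.matrix(rec[recording_channels(rec)]))

# rebuild a recording around new sample values, keeping metadata
.rec_update <- function(rec, samples_ct) {
  new_recording(t(samples_ct), fs = attr(rec, "fs"),
                channels = recording_channels(rec),
                label = attr(rec, "label"), seed = attr(rec, "seed"),
                subject_id = attr(rec, "subject_id"))
}

#' @export
print.occl_recording <- function(x, ...) {
  m <- recording_meta(x)
  cat(sprintf(
    "<occl_recording> %d channels x %d samples, fs = %g Hz (%.3g s), label = %s\n",
    m$n_channels, nrow(x), m$fs, m$duration_s, m$label
  ))
  NextMethod()
}

#' Plot a recording as stacked channel traces
#'
#' @param rec A recording tibble.
#' @param channels Optional subset of channel names to show.
#' @return A ggplot object, one facet per channel.
#' @export
plot_recording <- function(rec, channels = NULL) {
  channels <- channels %||% recording_channels(rec)
  long <- tidyr::pivot_longer(
    tibble::as_tibble(rec)[c("t_s", channels)],
    -"t_s", names_to = "site", values_to = "voltage"
  )
  long$site <- factor(long$site, levels = channels)
  ggplot2::ggplot(long, ggplot2::aes(.data$t_s, .data$voltage)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$site)) +
    ggplot2::labs(x = "time [s]", y = "voltage [V]") +
    ggplot2::theme_minimal(base_size = 9)
}
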