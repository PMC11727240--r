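# Windowed six-feature extraction. Conditioned recordings are cut into
# contiguous 1 s windows; windows whose peak amplitude clears 3x the noise
# floor are kept; each channel of a valid window yields six features:
# maximum, minimum, peak-to-valley interval (s), zero crossings, inflection
# points, and the absolute square value (energy, sum of squares).

.FEATURES <- c("max", "min", "pvi", "zc", "infl", "abs2")

#' Segment a recording into fixed-length windows
#'
#' Windows are contiguous and non-overlapping (stride = window length);
#' a trailing remainder shorter than one window is dropped.
#'
#' @param rec An `occl_recording`.
#' @param window_s Window length in seconds (default 1).
#' @return A tibble with one row per window: `window` (1-based index),
#'   `start_s`, and `data` (list column of sample matrices, channels in
#'   columns). Zero rows if the recording is shorter than one window.
#' @export
segment_windows <- function(rec, window_s = 1.0) {
  stopifnot(inherits(rec, "occl_recording"))
  fs <- recording_fs(rec)
  len <- floor(fs * window_s)
  if (len < 2) {
    stop("window of ", window_s, " s spans fewer than 2 samples at fs = ",
         fs, " Hz", call. = FALSE)
  }
  n_win <- floor(nrow(rec) / len)
  x <- as.matrix(rec[recording_channels(rec)])
  tibble::tibble(
    window = seq_len(n_win),
    start_s = (seq_len(n_win) - 1) * len / fs,
    data = lapply(seq_len(n_win), function(w) {
      x[((w - 1) * len + 1):(w * len), , drop = FALSE]
    })
  )
}

#' Window validity rule
#'
#' A window is valid when its largest absolute amplitude over all channels
#' reaches at least `3 * noise_floor` (boundary inclusive).
#'
#' @param window Numeric matrix (samples x channels) or vector.
#' @param noise_floor Nonnegative noise-floor estimate, volts.
#' @return Logical flag.
#' @export
window_is_valid <- function(window, noise_floor) {
  stopifnot(noise_floor >= 0)
  # inclusive boundary, robust to floating-point representation of 3x
  max(abs(window)) >= 3 * noise_floor * (1 - 1e-12)
}

#' Robust noise-floor estimate
#'
#' Median absolute deviation of all samples, scaled by 1.4826 so it is
#' consistent with a Gaussian standard deviation.
#'
#' @param rec An `occl_recording`.
#' @return Scalar noise floor in volts.
#' @export
noise_floor <- function(rec) {
  mad(as.matrix(rec[recording_channels(rec)]), constant = 1.4826)
}

#' Six-feature summary of a single-channel window
#'
#' @param x Numeric vector with at least 3 samples.
#' @param fs Sampling rate in Hz (converts the peak-to-valley interval to
#'   seconds).
#' @return Named numeric vector `(max, min, pvi, zc, infl, abs2)`:
#'   maximum; minimum; absolute time between the global maximum and global
#'   minimum (ties to the earliest index); zero crossings, counted as
#'   strict sign changes between consecutive nonzero samples; inflection
#'   points, counted as sign changes of the second difference; and the
#'   absolute square value (signal energy, sum of squared samples).
#' @export
#' @examples
#' extract_features(rep(2, 50), fs = 50)  # c(2, 2, 0, 0, 0, 200)
extract_features <- function(x, fs) {
  if (length(x) < 3) {
    stop("need at least 3 samples (second difference undefined)",
         call. = FALSE)
  }
  count_sign_changes <- function(v) {
    s <- sign(v)
    s <- s[s != 0]
    if (length(s) < 2) 0L else sum(diff(s) != 0)
  }
  # ties at the extrema go to the earliest index; values within 1e-9 of the
  # range of the extremum count as tied, so analytically equal peaks are
  # not ranked by floating-point rounding noise
  tol <- 1e-9 * max(max(x) - min(x), abs(max(x)), .Machine$double.xmin)
  i_max <- which(x >= max(x) - tol)[1]
  i_min <- which(x <= min(x) + tol)[1]
  c(
    max = max(x),
    min = min(x),
    pvi = abs(i_max - i_min) / fs,
    zc = count_sign_changes(x),
    infl = count_sign_changes(diff(x, differences = 2)),
    abs2 = sum(x^2)
  )
}

# feature matrix (windows x [channels*6]) for one recording; site-major,
# feature-minor column order
.window_features <- function(windows, channels, fs) {
  cols <- as.vector(t(outer(channels, .FEATURES, paste, sep = "_")))
  rows <- lapply(windows, function(w) {
    # vapply gives a 6 x n_channels matrix; column-major flattening yields
    # site-major, feature-minor order matching `cols`
    as.vector(vapply(seq_along(channels),
                     function(j) extract_features(w[, j], fs),
                     numeric(6)))
  })
  out <- do.call(rbind, rows)
  colnames(out) <- cols
  out
}

#' Build a labeled feature table from recordings
#'
#' Segments each recording, drops invalid windows (below 3x the per-
#' recording noise floor), extracts the six features per channel, and
#' stacks everything into one tibble. Column order is site-major,
#' feature-minor: `MAX_LCI_max, MAX_LCI_min, ..., MAN_RSM_abs2`.
#'
#' @param recordings List of `occl_recording`s sharing one channel layout.
#' @param noise_floor_v Fixed noise floor in volts, or `NULL` to estimate
#'   per recording via [noise_floor()].
#' @param aggregate `"per_recording_mean"` (default; one row per recording,
#'   features averaged over its valid windows) or `"per_window"` (one row
#'   per valid window).
#' @param window_s Window length in seconds.
#' @return A tibble with identifier columns `recording_id`, `label` (and
#'   `window`, `start_s` for `per_window`) followed by the feature
#'   columns. Recordings with no valid window are dropped with a warning;
#'   an empty result is an error.
#' @export
build_feature_table <- function(recordings, noise_floor_v = NULL,
                                aggregate = c("per_recording_mean",
                                              "per_window"),
                                window_s = 1.0) {
  aggregate <- match.arg(aggregate)
  stopifnot(length(recordings) >= 1)
  layouts <- unique(lapply(recordings, recording_channels))
  if (length(layouts) != 1) {
    stop("all recordings must share one channel layout; found ",
         length(layouts), " different layouts", call. = FALSE)
  }
  channels <- layouts[[1]]
  parts <- lapply(seq_along(recordings), function(i) {
    rec <- recordings[[i]]
    nf <- noise_floor_v %||% noise_floor(rec)
    segs <- segment_windows(rec, window_s)
    keep <- vapply(segs$data, window_is_valid, logical(1), noise_floor = nf)
    if (!any(keep)) {
      warning("recording ", attr(rec, "subject_id"), " (#", i,
              ") has no valid windows; excluded", call. = FALSE)
      return(NULL)
    }
    feats <- .window_features(segs$data[keep], channels, recording_fs(rec))
    id <- attr(rec, "subject_id")
    if (is.na(id)) id <- paste0("rec_", i)
    if (aggregate == "per_recording_mean") {
      dplyr::bind_cols(
        tibble::tibble(recording_id = id, label = attr(rec, "label")),
        tibble::as_tibble(as.data.frame(t(colMeans(feats))))
      )
    } else {
      dplyr::bind_cols(
        tibble::tibble(recording_id = id, label = attr(rec, "label"),
                       window = segs$window[keep],
                       start_s = segs$start_s[keep]),
        tibble::as_tibble(as.data.frame(feats))
      )
    }
  })
  out <- dplyr::bind_rows(parts)
  if (nrow(out) == 0) {
    stop("no recording produced a valid window; feature table is empty",
         call. = FALSE)
  }
  out
}

#' Feature column names of a table
#'
#' @param table A feature table.
#' @return Names of the numeric feature columns (identifier columns
#'   `recording_id`, `label`, `window`, `start_s` excluded).
#' @export
feature_columns <- function(table) {
  setdiff(names(table), c("recording_id", "label", "window", "start_s"))
}

#' Z-score normalisation with frozen statistics
#'
#' Centres and scales each feature column. Statistics are computed from
#' `table` itself (typically the training partition) unless `stats` is
#' supplied, in which case they are applied unchanged — held-out rows must
#' be normalised with training statistics to avoid leakage. Zero-variance
#' columns get scale 1 with a warning.
#'
#' @param table A feature table.
#' @param stats Optional statistics tibble from a previous call (attribute
#'   `"scaling"` of its result, or the `$stats` of [feature_scaling()]).
#' @return The normalised table, with the statistics attached as attribute
#'   `"scaling"`.
#' @export
normalize_features <- function(table, stats = NULL) {
  cols <- feature_columns(table)
  if (is.null(stats)) {
    if (nrow(table) < 2) {
      stop("need at least 2 rows to estimate normalisation statistics",
           call. = FALSE)
    }
    stats <- feature_scaling(table)
  }
  if (!all(cols %in% stats$column)) {
    stop("normalisation statistics do not cover all feature columns",
         call. = FALSE)
  }
  out <- table
  for (cc in cols) {
    s <- stats[stats$column == cc, ]
    out[[cc]] <- (table[[cc]] - s$mean) / s$scale
  }
  attr(out, "scaling") <- stats
  out
}

#' @rdname normalize_features
#' @export
feature_scaling <- function(table) {
  cols <- feature_columns(table)
  mu <- vapply(table[cols], mean, numeric(1))
  # population (divisor-n) standard deviation, consistent with the
  # divisor-n covariance convention used by pca_fit()
  sdv <- vapply(table[cols], function(x) sqrt(mean((x - mean(x))^2)),
                numeric(1))
  zero <- !is.finite(sdv) | sdv == 0
  if (any(zero)) {
    warning("zero-variance feature column(s) ",
            paste(cols[zero], collapse = ", "),
            "; using scale 1", call. = FALSE)
    sdv[zero] <- 1
  }
  tibble::tibble(column = cols, mean = unname(mu), scale = unname(sdv))
}
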