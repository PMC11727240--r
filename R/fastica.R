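# FastICA blind source separation for crosstalk-mixed sensor channels:
# centre + whiten via eigendecomposition of the channel covariance, then a
# symmetric fixed-point iteration with the log-cosh (tanh) contrast. The
# Amari index quantifies how close unmixing %*% mixing is to a scaled
# permutation (0 = perfect separation).

#' FastICA unmixing of a multichannel recording
#'
#' @param rec An `occl_recording` (channels are mixtures).
#' @param n_components Number of sources to extract (default: all
#'   channels).
#' @param seed Integer seed for the random orthogonal initial rotation.
#' @param tol Convergence tolerance on the rotation update.
#' @param max_iter Fixed-point iteration budget; on non-convergence the
#'   result is still returned with `converged = FALSE`.
#'
#' @return An object of class `occl_unmix`: `sources` (components x time,
#'   unit variance), `unmixing` (components x channels, so
#'   `sources = unmixing %*% centred_input`), `rotation` (orthonormal
#'   rows), `whitening`, `mean`, `n_iterations`, `converged`, plus the
#'   recording's `fs` and channel names.
#' @export
fastica_unmix <- function(rec, n_components = NULL, seed = 1, tol = 1e-6,
                          max_iter = 500) {
  stopifnot(inherits(rec, "occl_recording"))
  x <- .rec_matrix(rec)
  n_ch <- nrow(x)
  n_components <- n_components %||% n_ch
  if (n_components > n_ch) {
    stop("`n_components` (", n_components, ") exceeds channel count (",
         n_ch, ")", call. = FALSE)
  }
  if (ncol(x) < 2 * n_ch) {
    stop("recording too short for ICA (need well over ", 2 * n_ch,
         " samples)", call. = FALSE)
  }
  mu <- rowMeans(x)
  xc <- x - mu
  n <- ncol(xc)
  cov <- tcrossprod(xc) / n
  eg <- eigen(cov, symmetric = TRUE)
  if (eg$values[n_ch] < 1e-12 * max(eg$values[1], .Machine$double.eps)) {
    stop("channel covariance is rank-deficient (collinear or constant ",
         "channels); ICA requires linearly independent channels",
         call. = FALSE)
  }
  keep <- seq_len(n_components)
  K <- diag(1 / sqrt(eg$values[keep]), n_components) %*% t(eg$vectors[, keep, drop = FALSE])
  z <- K %*% xc

  sym_decorrelate <- function(w) {
    e <- eigen(tcrossprod(w), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-18)), nrow(w)) %*%
      t(e$vectors) %*% w
  }
  w <- withr::with_seed(as.integer(seed), {
    qr.Q(qr(matrix(rnorm(n_components^2), n_components)))
  })
  w <- sym_decorrelate(w)
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    wz <- w %*% z
    g <- tanh(wz)
    gprime <- rowMeans(1 - g^2)
    w_new <- tcrossprod(g, z) / n - diag(gprime, n_components) %*% w
    w_new <- sym_decorrelate(w_new)
    delta <- max(abs(abs(diag(w_new %*% t(w))) - 1))
    w <- w_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  sources <- w %*% z
  structure(
    list(sources = sources, unmixing = w %*% K, rotation = w, whitening = K,
         mean = mu, n_iterations = it, converged = converged,
         fs = recording_fs(rec), channels = recording_channels(rec),
         label = recording_label(rec)),
    class = "occl_unmix"
  )
}

#' @export
print.occl_unmix <- function(x, ...) {
  cat(sprintf("<occl_unmix> %d sources x %d samples, %d iterations, %s\n",
              nrow(x$sources), ncol(x$sources), x$n_iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Re-align ICA sources to reference channels
#'
#' ICA recovers sources only up to permutation, sign and scale. This
#' assigns each source to the reference channel with which its absolute
#' correlation is largest (greedy, descending, each channel used once),
#' flips signs so correlations are positive, and by default restores each
#' source's physical scale by least-squares regression onto its reference
#' channel — without that step the unit-variance ICA output would discard
#' the per-site amplitude differences that carry the class signal.
#'
#' @param result An `occl_unmix`.
#' @param reference The recording to align against (typically the pre-ICA
#'   conditioned recording), same channel count and length.
#' @param rescale Restore per-source amplitude via least squares
#'   (default `TRUE`).
#' @return An `occl_recording` with the reference's channel map and
#'   metadata.
#' @export
align_sources <- function(result, reference, rescale = TRUE) {
  stopifnot(inherits(result, "occl_unmix"),
            inherits(reference, "occl_recording"))
  ref <- .rec_matrix(reference)
  src <- result$sources
  if (nrow(ref) != nrow(src) || ncol(ref) != ncol(src)) {
    stop("reference dimensions (", nrow(ref), " x ", ncol(ref),
         ") do not match sources (", nrow(src), " x ", ncol(src), ")",
         call. = FALSE)
  }
  cm <- suppressWarnings(cor(t(src), t(ref)))   # sources x channels
  cm[!is.finite(cm)] <- 0
  if (max(abs(cm)) < 1e-8) {
    stop("sources cannot be aligned: all source-reference correlations ",
         "are ~0 (degenerate reference?)", call. = FALSE)
  }
  n <- nrow(src)
  assign_ch <- rep(NA_integer_, n)
  absc <- abs(cm)
  for (k in seq_len(n)) {
    best <- arrayInd(which.max(absc), dim(absc))
    assign_ch[best[1]] <- best[2]
    absc[best[1], ] <- -Inf
    absc[, best[2]] <- -Inf
  }
  out <- matrix(0, n, ncol(ref))
  for (i in seq_len(n)) {
    j <- assign_ch[i]
    s <- src[i, ] * sign(cm[i, j])
    if (rescale) {
      beta <- sum((ref[j, ] - mean(ref[j, ])) * (s - mean(s))) /
        max(sum((s - mean(s))^2), .Machine$double.eps)
      s <- s * beta
    }
    out[j, ] <- s
  }
  new_recording(t(out), fs = attr(reference, "fs"),
                channels = recording_channels(reference),
                label = attr(reference, "label"),
                seed = attr(reference, "seed"),
                subject_id = attr(reference, "subject_id"))
}

#' Amari separation index
#'
#' Permutation- and scale-invariant distance of a square matrix from a
#' scaled permutation, normalised to `[0, n - 1]`. For a separation
#' experiment evaluate it on `unmixing %*% true_mixing`.
#'
#' @param P Square numeric matrix with no all-zero row or column.
#' @return A scalar; 0 iff `P` is a scaled permutation matrix.
#' @export
#' @examples
#' amari_index(diag(4))              # 0
#' amari_index(matrix(1, 2, 2))      # 1
amari_index <- function(P) {
  P <- as.matrix(P)
  if (nrow(P) != ncol(P)) stop("`P` must be square", call. = FALSE)
  a <- abs(P)
  if (any(rowSums(a) == 0) || any(colSums(a) == 0)) {
    stop("`P` has an all-zero row or column", call. = FALSE)
  }
  n <- nrow(P)
  row_term <- sum(rowSums(a) / apply(a, 1, max) - 1)
  col_term <- sum(colSums(a) / apply(a, 2, max) - 1)
  (row_term + col_term) / (2 * n)
}
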