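# Principal component analysis from first principles: centre the data,
# form the divisor-n covariance U = (1/n) * sum(phi_i phi_i^T), take its
# top-k eigenpairs, and project y_i = W^T (x_i - x_mean).

#' Fit a principal component model
#'
#' @param x A data frame (feature columns used, identifier columns
#'   `recording_id`/`label`/`window`/`start_s` ignored) or numeric matrix,
#'   rows = observations.
#' @param k Number of components to retain; silently truncated (with a
#'   warning) to the number of strictly positive eigenvalues.
#'
#' @return An object of class `occl_pca`: `mean` (column means), `w`
#'   (features x k eigenvector matrix, orthonormal columns, each with its
#'   largest-magnitude entry made positive), `lambda` (all eigenvalues of
#'   the covariance, non-increasing, clipped at 0), `k`, and `features`
#'   (column names).
#' @export
#' @examples
#' m <- pca_fit(data.frame(a = c(1, -1), b = c(1, -1)), k = 1)
#' m$lambda[1]   # 2
pca_fit <- function(x, k = 3) {
  xm <- .numeric_matrix(x)
  stopifnot(nrow(xm) >= 2, k >= 1)
  n <- nrow(xm)
  mu <- colMeans(xm)
  phi <- sweep(xm, 2, mu)
  u <- crossprod(phi) / n
  eg <- eigen(u, symmetric = TRUE)
  lambda <- pmax(eg$values, 0)
  n_pos <- sum(eg$values > 1e-12 * max(eg$values[1], .Machine$double.eps))
  if (k > n_pos) {
    warning("k = ", k, " exceeds the ", n_pos,
            " strictly positive eigenvalues; truncating", call. = FALSE)
    k <- n_pos
  }
  w <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    lead <- which.max(abs(w[, j]))
    if (w[lead, j] < 0) w[, j] <- -w[, j]
  }
  rownames(w) <- colnames(xm)
  structure(
    list(mean = mu, w = w, lambda = lambda, k = k, features = colnames(xm)),
    class = "occl_pca"
  )
}

#' Project data onto a fitted principal component model
#'
#' Computes `y_i = W^T (x_i - x_mean)`. When `x` is a data frame its
#' identifier columns (e.g. `label`) are carried through alongside the
#' scores.
#'
#' @param model An `occl_pca`.
#' @param x Data with the same feature columns the model was fitted on.
#' @return A tibble with any identifier columns followed by `PC1..PCk`.
#' @export
pca_project <- function(model, x) {
  stopifnot(inherits(model, "occl_pca"))
  xm <- .numeric_matrix(x)
  if (!identical(colnames(xm), model$features)) {
    if (!all(model$features %in% colnames(xm))) {
      stop("projection data lacks feature column(s): ",
           paste(setdiff(model$features, colnames(xm)), collapse = ", "),
           call. = FALSE)
    }
    xm <- xm[, model$features, drop = FALSE]
  }
  scores <- sweep(xm, 2, model$mean) %*% model$w
  colnames(scores) <- paste0("PC", seq_len(model$k))
  dplyr::bind_cols(.id_columns(x), tibble::as_tibble(as.data.frame(scores)))
}

#' @export
print.occl_pca <- function(x, ...) {
  cat(sprintf("<occl_pca> %d features, k = %d; leading eigenvalues: %s\n",
              length(x$features), x$k,
              paste(signif(head(x$lambda, 5), 4), collapse = ", ")))
  invisible(x)
}

#' @export
tidy.occl_pca <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$lambda),
    eigenvalue = x$lambda,
    variance_explained = x$lambda / sum(x$lambda)
  )
}

#' @export
glance.occl_pca <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$features),
    k = x$k,
    total_variance = sum(x$lambda),
    variance_retained = sum(x$lambda[seq_len(x$k)]) / sum(x$lambda)
  )
}

#' @export
autoplot.occl_pca <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$component, .data$variance_explained)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "component", y = "fraction of variance") +
    ggplot2::theme_minimal()
}

# --- shared helpers ----------------------------------------------------------

.ID_COLS <- c("recording_id", "label", "window", "start_s")

.numeric_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
    return(x)
  }
  cols <- setdiff(names(x), .ID_COLS)
  as.matrix(as.data.frame(x)[cols])
}

.id_columns <- function(x) {
  if (is.matrix(x)) return(tibble::tibble(.rows = nrow(x)))
  tibble::as_tibble(as.data.frame(x)[intersect(.ID_COLS, names(x))])
}
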