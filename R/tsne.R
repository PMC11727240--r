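# t-distributed stochastic neighbour embedding from first principles:
# Gaussian conditional affinities with per-point bandwidths solved by
# entropy bisection, symmetrised p_ij = (p_{j|i} + p_{i|j}) / (2N),
# Student-t low-dimensional similarities, and gradient descent on the
# KL divergence with momentum and early exaggeration.

#' High-dimensional affinities for t-SNE
#'
#' For each point the Gaussian bandwidth `sigma_i` is found by bisection so
#' that the perplexity (2^entropy) of the conditional distribution
#' `p_{.|i}` matches the target within 1e-3 (at most 64 iterations,
#' `sigma` bracketed in `[1e-20, 1e20]`). Affinities are then symmetrised
#' and normalised to sum to one.
#'
#' @param x Data frame or matrix of observations (identifier columns
#'   ignored); at least 3 rows.
#' @param perplexity Target perplexity, must be below the number of rows.
#' @return A list with `p` (symmetric affinity matrix, zero diagonal,
#'   entries summing to 1) and `sigma` (per-point bandwidths).
#' @export
tsne_affinities <- function(x, perplexity = 30) {
  xm <- .numeric_matrix(x)
  n <- nrow(xm)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  if (perplexity >= n) {
    stop("`perplexity` (", perplexity, ") must be below the number of ",
         "points (", n, ")", call. = FALSE)
  }
  sq <- rowSums(xm^2)
  d2 <- pmax(outer(sq, sq, `+`) - 2 * tcrossprod(xm), 0)
  target <- log2(perplexity)
  p_cond <- matrix(0, n, n)
  sigma <- numeric(n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    if (all(di <= 0)) {
      stop("point ", i, " coincides with every other point; affinities ",
           "undefined (remove duplicates)", call. = FALSE)
    }
    # bisect on the precision beta = 1 / (2 sigma^2): expand the bracket
    # geometrically until the target entropy is straddled, then halve
    beta <- 1 / median(di)
    betamin <- -Inf
    betamax <- Inf
    p <- NULL
    for (iter in 1:64) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw <= .Machine$double.xmin) {
        h <- 0
        p <- as.numeric(di == min(di)) / sum(di == min(di))
      } else {
        p <- w / sw
        h <- -sum(p[p > 0] * log2(p[p > 0]))
      }
      if (abs(h - target) < 1e-3) break
      if (h > target) {          # sigma too large -> increase beta
        betamin <- beta
        beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
      } else {
        betamax <- beta
        beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
      }
      beta <- min(max(beta, 1 / (2 * 1e40)), 1 / (2 * 1e-40))
    }
    sigma[i] <- sqrt(1 / (2 * beta))
    p_cond[i, -i] <- p
  }
  p <- (p_cond + t(p_cond)) / (2 * n)
  diag(p) <- 0
  list(p = p, sigma = sigma)
}

#' Kullback-Leibler divergence between affinity matrices
#'
#' `C = sum_{i != j} p_ij log(p_ij / q_ij)`, with both arguments floored at
#' 1e-12 so the divergence is finite; zero when `P = Q`.
#'
#' @param p,q Affinity matrices of equal dimension.
#' @return Nonnegative scalar.
#' @export
kl_divergence <- function(p, q) {
  pf <- pmax(p, 1e-12)
  qf <- pmax(q, 1e-12)
  off <- row(p) != col(p)
  sum(p[off] * log(pf[off] / qf[off]))
}

# Student-t similarities of a coordinate matrix; returns list(q, num) where
# num are the unnormalised (1 + d^2)^-1 weights
.tsne_q <- function(y) {
  sq <- rowSums(y^2)
  num <- 1 / (1 + pmax(outer(sq, sq, `+`) - 2 * tcrossprod(y), 0))
  diag(num) <- 0
  list(q = num / sum(num), num = num)
}

#' Embed data with t-SNE
#'
#' Gradient descent on the KL divergence between high- and low-dimensional
#' affinities, with early exaggeration (P x 12 for the first 250
#' iterations) and momentum 0.5 switching to 0.8 after iteration 250.
#' The reported cost trace is always computed against the un-exaggerated P.
#'
#' @param x Data frame or matrix (identifier columns carried into the
#'   result).
#' @param dims Output dimensionality, 2 or 3 (default 3).
#' @param perplexity Target perplexity.
#' @param iters Gradient-descent iterations, >= 50.
#' @param learning_rate Step size.
#' @param seed Seed for the small-Gaussian initialisation; identical seeds
#'   give identical embeddings.
#'
#' @return An object of class `occl_tsne`: `y` (coordinates), `p`, `q`,
#'   `sigma`, `cost` (final KL), `trace` (KL per iteration), `ids`
#'   (identifier columns of `x`), and the call parameters.
#' @export
tsne_embed <- function(x, dims = 3, perplexity = 30, iters = 1000,
                       learning_rate = 200, seed = 1) {
  stopifnot(dims %in% c(2, 3), iters >= 50)
  aff <- tsne_affinities(x, perplexity)
  p <- aff$p
  n <- nrow(p)
  y <- withr::with_seed(as.integer(seed),
                        matrix(rnorm(n * dims, sd = 1e-4), n, dims))
  exaggeration <- 12
  stop_exagg <- min(250, floor(iters / 2))
  momentum <- 0.5
  vel <- matrix(0, n, dims)
  trace <- numeric(iters)
  for (it in seq_len(iters)) {
    p_eff <- if (it <= stop_exagg) p * exaggeration else p
    qq <- .tsne_q(y)
    trace[it] <- kl_divergence(p, qq$q)
    if (!is.finite(trace[it])) {
      stop("t-SNE cost became non-finite at iteration ", it,
           "; try a smaller learning rate", call. = FALSE)
    }
    if (it > stop_exagg) momentum <- 0.8
    mult <- (p_eff - qq$q) * qq$num
    grad <- 4 * (diag(rowSums(mult)) - mult) %*% y
    vel <- momentum * vel - learning_rate * grad
    y <- y + vel
    y <- sweep(y, 2, colMeans(y))
  }
  qq <- .tsne_q(y)
  final_c <- kl_divergence(p, qq$q)
  colnames(y) <- paste0("TSNE", seq_len(dims))
  structure(
    list(y = y, p = p, q = qq$q, sigma = aff$sigma, cost = final_c,
         trace = trace, ids = .id_columns(x), dims = dims,
         perplexity = perplexity, iters = iters,
         learning_rate = learning_rate, seed = seed),
    class = "occl_tsne"
  )
}

#' @export
print.occl_tsne <- function(x, ...) {
  cat(sprintf(
    "<occl_tsne> %d points -> %dD, perplexity %g, %d iters, KL %.4f\n",
    nrow(x$y), x$dims, x$perplexity, x$iters, x$cost
  ))
  invisible(x)
}

#' @export
tidy.occl_tsne <- function(x, ...) {
  dplyr::bind_cols(x$ids, tibble::as_tibble(as.data.frame(x$y)))
}

#' @export
glance.occl_tsne <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$y), dims = x$dims, perplexity = x$perplexity,
    iters = x$iters, kl_initial = x$trace[1], kl_final = x$cost
  )
}

#' @export
autoplot.occl_tsne <- function(object, ...) {
  d <- tidy(object)
  aes <- if ("label" %in% names(d)) {
    ggplot2::aes(.data$TSNE1, .data$TSNE2, colour = .data$label)
  } else {
    ggplot2::aes(.data$TSNE1, .data$TSNE2)
  }
  ggplot2::ggplot(d, aes) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2") +
    ggplot2::theme_minimal()
}

#' Mean silhouette width of labeled coordinates
#'
#' Plain silhouette score on Euclidean distances: for each point, `a` is
#' its mean distance to its own class, `b` the smallest mean distance to
#' another class, and the width is `(b - a) / max(a, b)`.
#'
#' @param coords Matrix or data frame of coordinates (identifier columns
#'   ignored).
#' @param labels Class label per row (>= 2 distinct values).
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
silhouette_score <- function(coords, labels) {
  y <- .numeric_matrix(coords)
  labels <- as.character(labels)
  stopifnot(nrow(y) == length(labels), length(unique(labels)) >= 2)
  d <- as.matrix(stats::dist(y))
  widths <- vapply(seq_len(nrow(y)), function(i) {
    own <- labels == labels[i]
    own[i] <- FALSE
    if (!any(own)) return(0)
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(widths)
}
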