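# Balanced seven-model classification benchmark: class-balanced 80:20
# split, fixed seeded hyperparameters per model, confusion matrix /
# one-vs-rest ROC-AUC / precision-recall / F1 reporting, and per-tooth-site
# permutation importance.

.MODEL_NAMES <- c("xgboost", "svm", "random_forest", "bp_nn", "mlp", "knn",
                  "decision_tree")

#' Balanced stratified train/test split
#'
#' Classes are first downsampled (seeded, without replacement) to the
#' minimum class count so every class is equally represented, then split
#' per class into train and test at the given ratio (`round(ratio * m)`
#' train rows per class, at least one test row).
#'
#' @param table Feature table with a `label` column; >= 2 classes, every
#'   class >= 5 rows.
#' @param ratio Training fraction (default 0.8).
#' @param seed Integer seed; identical seeds give identical plans.
#' @return An object of class `occl_split`: integer row indices `train`
#'   and `test` into `table`, plus `seed` and a per-class count tibble.
#' @export
balanced_split <- function(table, ratio = 0.8, seed = 1) {
  stopifnot("label" %in% names(table), ratio > 0, ratio < 1)
  labels <- as.character(table$label)
  counts <- table(labels)
  if (length(counts) < 2) stop("need at least 2 classes", call. = FALSE)
  small <- names(counts)[counts < 5]
  if (length(small) > 0) {
    stop("class(es) with fewer than 5 rows: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  m <- min(counts)
  n_train <- max(1, min(round(ratio * m), m - 1))
  plan <- withr::with_seed(as.integer(seed), {
    train <- integer(0)
    test <- integer(0)
    for (cl in names(counts)) {
      rows <- which(labels == cl)
      rows <- sample(rows, m)            # downsample + shuffle
      train <- c(train, rows[seq_len(n_train)])
      test <- c(test, rows[(n_train + 1):m])
    }
    list(train = sort(train), test = sort(test))
  })
  structure(
    list(train = plan$train, test = plan$test, seed = as.integer(seed),
         counts = tibble::tibble(class = names(counts),
                                 available = as.integer(counts),
                                 used = m, train = n_train,
                                 test = m - n_train)),
    class = "occl_split"
  )
}

#' @export
print.occl_split <- function(x, ...) {
  cat(sprintf("<occl_split> %d train / %d test rows (seed %d)\n",
              length(x$train), length(x$test), x$seed))
  print(x$counts)
  invisible(x)
}

# --- model fitting -----------------------------------------------------------

# two-hidden-layer softmax perceptron trained with full-batch Adam; written
# in-package because no installed package offers a seeded two-layer MLP
.fit_mlp <- function(x, y_int, n_classes, hidden = c(64, 32), epochs = 400,
                     lr = 5e-3, seed = 1) {
  sizes <- c(ncol(x), hidden, n_classes)
  params <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(length(sizes) - 1), function(l) {
      list(W = matrix(rnorm(sizes[l] * sizes[l + 1],
                            sd = sqrt(2 / sizes[l])),
                      sizes[l], sizes[l + 1]),
           b = rep(0, sizes[l + 1]))
    })
  })
  onehot <- diag(n_classes)[y_int, , drop = FALSE]
  mom <- lapply(params, function(p) list(mW = p$W * 0, vW = p$W * 0,
                                         mb = p$b * 0, vb = p$b * 0))
  relu <- function(z) pmax(z, 0)
  n <- nrow(x)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  for (ep in seq_len(epochs)) {
    acts <- list(x)
    zs <- list()
    for (l in seq_along(params)) {
      z <- sweep(acts[[l]] %*% params[[l]]$W, 2, params[[l]]$b, `+`)
      zs[[l]] <- z
      acts[[l + 1]] <- if (l < length(params)) relu(z) else z
    }
    logits <- acts[[length(acts)]]
    logits <- logits - apply(logits, 1, max)
    expz <- exp(logits)
    probs <- expz / rowSums(expz)
    delta <- (probs - onehot) / n
    for (l in rev(seq_along(params))) {
      gW <- crossprod(acts[[l]], delta)
      gb <- colSums(delta)
      if (l > 1) {
        delta <- (delta %*% t(params[[l]]$W)) * (zs[[l - 1]] > 0)
      }
      m <- mom[[l]]
      m$mW <- beta1 * m$mW + (1 - beta1) * gW
      m$vW <- beta2 * m$vW + (1 - beta2) * gW^2
      m$mb <- beta1 * m$mb + (1 - beta1) * gb
      m$vb <- beta2 * m$vb + (1 - beta2) * gb^2
      mom[[l]] <- m
      corr1 <- 1 - beta1^ep
      corr2 <- 1 - beta2^ep
      params[[l]]$W <- params[[l]]$W -
        lr * (m$mW / corr1) / (sqrt(m$vW / corr2) + eps)
      params[[l]]$b <- params[[l]]$b -
        lr * (m$mb / corr1) / (sqrt(m$vb / corr2) + eps)
    }
  }
  list(params = params)
}

.predict_mlp <- function(fit, x) {
  a <- x
  np <- length(fit$params)
  for (l in seq_len(np)) {
    a <- sweep(a %*% fit$params[[l]]$W, 2, fit$params[[l]]$b, `+`)
    if (l < np) a <- pmax(a, 0)
  }
  a <- a - apply(a, 1, max)
  expz <- exp(a)
  expz / rowSums(expz)
}

# distance-based kNN returning per-class vote fractions
.knn_scores <- function(train_x, train_y, test_x, levels, k = 5) {
  d2 <- outer(rowSums(test_x^2), rowSums(train_x^2), `+`) -
    2 * tcrossprod(test_x, train_x)
  probs <- t(apply(d2, 1, function(row) {
    nb <- train_y[order(row)[seq_len(k)]]
    tabulate(factor(nb, levels = levels), nbins = length(levels)) / k
  }))
  colnames(probs) <- levels
  probs
}

#' Fit the seven-model classification suite
#'
#' Models and fixed settings: gradient-boosted trees (xgboost, 300 rounds,
#' depth 6, eta 0.3), RBF-kernel SVM with probability estimates (e1071),
#' random forest (ranger, 500 probability trees), a one-hidden-layer
#' back-propagation ("BP") softmax network of 64 units, a two-hidden-layer
#' 64/32 multilayer perceptron (both trained by the in-package full-batch
#' Adam backprop routine), 5-nearest-neighbour voting, and a CART decision
#' tree (rpart). All stochastic fits are seeded;
#' refitting with the same seed reproduces identical predictions. A model
#' that fails to fit is recorded and skipped rather than aborting the
#' suite.
#'
#' @param train Normalised feature table with a `label` column.
#' @param models Subset of
#'   `c("xgboost", "svm", "random_forest", "bp_nn", "mlp", "knn",
#'   "decision_tree")`.
#' @param seed Integer seed.
#' @return An object of class `occl_suite`: fitted models, class levels,
#'   feature column names, seed and any per-model failure messages.
#' @export
train_suite <- function(train, models = .MODEL_NAMES, seed = 1) {
  models <- match.arg(models, .MODEL_NAMES, several.ok = TRUE)
  if (nrow(train) == 0) stop("empty training set", call. = FALSE)
  cols <- feature_columns(train)
  x <- as.matrix(train[cols])
  y <- factor(as.character(train$label))
  levels <- levels(y)
  y_int <- as.integer(y)
  sub <- .derive_seeds(seed, length(.MODEL_NAMES))
  names(sub) <- .MODEL_NAMES
  fits <- list()
  failures <- character(0)
  fit_one <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[name]] <<- conditionMessage(res)
    } else {
      fits[[name]] <<- res
    }
  }
  if ("xgboost" %in% models) {
    fit_one("xgboost", withr::with_seed(sub[["xgboost"]], {
      dtrain <- xgboost::xgb.DMatrix(x, label = y_int - 1)
      xgboost::xgb.train(
        params = list(objective = "multi:softprob",
                      num_class = length(levels), max_depth = 6,
                      eta = 0.3, nthread = 1, seed = sub[["xgboost"]]),
        data = dtrain, nrounds = 300, verbose = 0
      )
    }))
  }
  if ("svm" %in% models) {
    fit_one("svm", withr::with_seed(sub[["svm"]], {
      e1071::svm(x, y, kernel = "radial", probability = TRUE)
    }))
  }
  if ("random_forest" %in% models) {
    fit_one("random_forest", {
      ranger::ranger(x = x, y = y, num.trees = 500, probability = TRUE,
                     seed = sub[["random_forest"]], num.threads = 1)
    })
  }
  if ("bp_nn" %in% models) {
    fit_one("bp_nn", .fit_mlp(x, y_int, length(levels), hidden = 64,
                              seed = sub[["bp_nn"]]))
  }
  if ("mlp" %in% models) {
    fit_one("mlp", .fit_mlp(x, y_int, length(levels), hidden = c(64, 32),
                            seed = sub[["mlp"]]))
  }
  if ("knn" %in% models) {
    fit_one("knn", list(x = x, y = y, k = 5))
  }
  if ("decision_tree" %in% models) {
    fit_one("decision_tree", withr::with_seed(sub[["decision_tree"]], {
      df <- data.frame(.label = y, x, check.names = FALSE)
      rpart::rpart(.label ~ ., data = df, method = "class")
    }))
  }
  structure(
    list(fits = fits, models = names(fits), levels = levels,
         features = cols, seed = as.integer(seed), failures = failures),
    class = "occl_suite"
  )
}

# per-model probability matrix (rows sum to 1, columns = suite levels)
.predict_scores <- function(suite, name, x) {
  fit <- suite$fits[[name]]
  levels <- suite$levels
  probs <- switch(name,
    xgboost = {
      pr <- predict(fit, xgboost::xgb.DMatrix(x))
      if (is.matrix(pr)) pr else matrix(pr, nrow(x), length(levels),
                                        byrow = TRUE)
    },
    svm = {
      pr <- attr(predict(fit, x, probability = TRUE), "probabilities")
      pr[, levels, drop = FALSE]
    },
    random_forest = predict(fit, data = x, num.threads = 1)$predictions,
    bp_nn = .predict_mlp(fit, x),
    mlp = .predict_mlp(fit, x),
    knn = .knn_scores(fit$x, fit$y, x, levels, fit$k),
    decision_tree = predict(fit, newdata = as.data.frame(x), type = "prob")
  )
  probs <- as.matrix(probs)
  if (is.null(colnames(probs)) || !all(levels %in% colnames(probs))) {
    colnames(probs) <- levels
  }
  probs[, levels, drop = FALSE]
}

#' Predict classes and scores from a fitted suite
#'
#' @param suite An `occl_suite`.
#' @param table Feature table with the suite's feature columns.
#' @return Named list per model with `class` (factor) and `scores`
#'   (probability matrix).
#' @export
predict_suite <- function(suite, table) {
  x <- as.matrix(table[suite$features])
  out <- lapply(suite$models, function(name) {
    scores <- .predict_scores(suite, name, x)
    cls <- factor(suite$levels[max.col(scores, ties.method = "first")],
                  levels = suite$levels)
    list(class = cls, scores = scores)
  })
  names(out) <- suite$models
  out
}

# --- metrics -----------------------------------------------------------------

#' One-vs-rest AUC from a rank statistic
#'
#' Mann-Whitney form: the probability that a random positive outranks a
#' random negative, with ties counted half.
#'
#' @param scores Numeric score for the positive class.
#' @param positive Logical vector marking positives.
#' @return AUC in `[0, 1]`, or `NA` if either group is empty.
#' @export
rank_auc <- function(scores, positive) {
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

.metrics_one <- function(truth, pred, scores, levels) {
  cm <- table(factor(truth, levels = levels),
              factor(pred, levels = levels))
  per_class <- lapply(levels, function(cl) {
    tp <- cm[cl, cl]
    fp <- sum(cm[, cl]) - tp
    fn <- sum(cm[cl, ]) - tp
    precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
    recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    auc <- if (is.null(scores)) NA_real_ else
      rank_auc(scores[, cl], truth == cl)
    tibble::tibble(class = cl, precision = precision, recall = recall,
                   f1 = f1, auc = auc)
  })
  per_class <- dplyr::bind_rows(per_class)
  list(
    confusion = unclass(cm),
    accuracy = sum(diag(cm)) / sum(cm),
    per_class = per_class,
    macro_f1 = mean(per_class$f1),
    macro_auc = mean(per_class$auc)
  )
}

#' Evaluate a fitted suite on held-out rows
#'
#' @param suite An `occl_suite`.
#' @param test Non-empty feature table with `label` and the suite's
#'   feature columns.
#' @return An object of class `occl_report`: per-model accuracy, confusion
#'   matrix (rows = truth), per-class precision/recall/F1 and one-vs-rest
#'   rank-statistic AUC, macro averages, plus split sizes and seed.
#' @export
evaluate_suite <- function(suite, test) {
  stopifnot(inherits(suite, "occl_suite"), nrow(test) > 0,
            "label" %in% names(test))
  preds <- predict_suite(suite, test)
  truth <- factor(as.character(test$label), levels = suite$levels)
  per_model <- lapply(suite$models, function(name) {
    .metrics_one(truth, preds[[name]]$class, preds[[name]]$scores,
                 suite$levels)
  })
  names(per_model) <- suite$models
  structure(
    list(models = per_model, levels = suite$levels,
         n_test = nrow(test), seed = suite$seed,
         failures = suite$failures),
    class = "occl_report"
  )
}

#' @export
print.occl_report <- function(x, ...) {
  cat(sprintf("<occl_report> %d models on %d test rows\n",
              length(x$models), x$n_test))
  print(glance(x))
  invisible(x)
}

#' @export
glance.occl_report <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$models), function(m) {
    tibble::tibble(model = m, accuracy = x$models[[m]]$accuracy,
                   macro_f1 = x$models[[m]]$macro_f1,
                   macro_auc = x$models[[m]]$macro_auc)
  }))
}

#' @export
tidy.occl_report <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$models), function(m) {
    dplyr::bind_cols(tibble::tibble(model = m), x$models[[m]]$per_class)
  }))
}

#' @export
autoplot.occl_report <- function(object, model = NULL, ...) {
  model <- model %||% names(object$models)[1]
  cm <- object$models[[model]]$confusion
  d <- tibble::as_tibble(as.data.frame(as.table(cm)))
  names(d) <- c("truth", "predicted", "count")
  ggplot2::ggplot(d, ggplot2::aes(.data$predicted, .data$truth,
                                  fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(title = paste0("Confusion matrix (", model, ")")) +
    ggplot2::theme_minimal()
}

#' Serialise a report to JSON
#'
#' @param report An `occl_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- list(
    n_test = report$n_test, seed = report$seed, levels = report$levels,
    models = lapply(report$models, function(m) {
      list(accuracy = m$accuracy, macro_f1 = m$macro_f1,
           macro_auc = m$macro_auc, confusion = m$confusion,
           per_class = m$per_class)
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", matrix = "rowmajor")
  invisible(path)
}

# --- permutation importance --------------------------------------------------

#' Per-tooth-site permutation importance
#'
#' Shuffles one feature column at a time in the held-out rows and records
#' the drop in accuracy (mean over `n_repeats` seeded shuffles); column
#' importances are then summed over the six features of each tooth site.
#' Per-class values use one-vs-rest accuracy of that class. Note that
#' perfectly correlated columns share credit: duplicating a column roughly
#' halves each copy's importance.
#'
#' @param suite An `occl_suite`.
#' @param test Feature table with >= 20 rows.
#' @param model Model name within the suite (default `"xgboost"`).
#' @param n_repeats Shuffles per column, >= 2.
#' @param seed Integer seed.
#' @return A tibble `site`, `class` (`"overall"` plus each class),
#'   `importance` (mean accuracy drop, summed over the site's features)
#'   and `se` (standard error across repeats, summed in quadrature).
#' @export
site_importance <- function(suite, test, model = "xgboost", n_repeats = 20,
                            seed = 1) {
  stopifnot(inherits(suite, "occl_suite"))
  if (n_repeats < 2) stop("`n_repeats` must be >= 2", call. = FALSE)
  if (nrow(test) < 20) {
    stop("need at least 20 held-out rows for a stable importance estimate",
         call. = FALSE)
  }
  if (!model %in% suite$models) {
    stop("model ", model, " not in suite (have: ",
         paste(suite$models, collapse = ", "), ")", call. = FALSE)
  }
  x <- as.matrix(test[suite$features])
  truth <- factor(as.character(test$label), levels = suite$levels)
  predict_cls <- function(xm) {
    scores <- .predict_scores(suite, model, xm)
    factor(suite$levels[max.col(scores, ties.method = "first")],
           levels = suite$levels)
  }
  base_pred <- predict_cls(x)
  acc_views <- function(pred) {
    c(overall = mean(pred == truth),
      stats::setNames(
        vapply(suite$levels,
               function(cl) mean((pred == cl) == (truth == cl)),
               numeric(1)),
        suite$levels))
  }
  base_acc <- acc_views(base_pred)
  perm_seeds <- .derive_seeds(seed, n_repeats)
  n_feat <- length(suite$features)
  drops <- array(NA_real_,
                 c(n_feat, n_repeats, length(base_acc)),
                 dimnames = list(suite$features, NULL, names(base_acc)))
  for (r in seq_len(n_repeats)) {
    perm <- withr::with_seed(perm_seeds[r], sample.int(nrow(x)))
    for (j in seq_len(n_feat)) {
      xp <- x
      xp[, j] <- x[perm, j]
      drops[j, r, ] <- base_acc - acc_views(predict_cls(xp))
    }
  }
  col_imp <- apply(drops, c(1, 3), mean)
  col_se <- apply(drops, c(1, 3), function(v) sd(v) / sqrt(length(v)))
  site_of <- sub("_(max|min|pvi|zc|infl|abs2)$", "", suite$features)
  purrr::map_dfr(unique(site_of), function(s) {
    rows <- site_of == s
    purrr::map_dfr(colnames(col_imp), function(view) {
      tibble::tibble(site = s, class = view,
                     importance = sum(col_imp[rows, view]),
                     se = sqrt(sum(col_se[rows, view]^2)))
    })
  })
}
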