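test_that("balanced splits downsample and stratify at 80:20", {
  tab <- toy_feature_table(20, c("A", "B", "C", "D", "E"))
  sp <- balanced_split(tab, seed = 1)
  expect_length(sp$train, 5 * 16)
  expect_length(sp$test, 5 * 4)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_true(all(table(tab$label[sp$train]) == 16))
  expect_true(all(table(tab$label[sp$test]) == 4))
  # unequal counts 30/20/10 downsample to 10 each, 8 train / 2 test
  tab2 <- dplyr::bind_rows(toy_feature_table(30, "A"),
                           toy_feature_table(20, "B"),
                           toy_feature_table(10, "C"))
  sp2 <- balanced_split(tab2, seed = 3)
  expect_true(all(table(tab2$label[sp2$train]) == 8))
  expect_true(all(table(tab2$label[sp2$test]) == 2))
  # determinism
  expect_identical(balanced_split(tab, seed = 9)[c("train", "test")],
                   balanced_split(tab, seed = 9)[c("train", "test")])
  expect_error(balanced_split(toy_feature_table(4, c("A", "B")), seed = 1),
               "fewer than 5 rows: A")
  expect_error(balanced_split(toy_feature_table(10, "A"), seed = 1),
               "at least 2 classes")
})

test_that("every model separates a perfectly separable two-class problem", {
  tab <- tibble::tibble(
    recording_id = sprintf("r%02d", 1:40),
    label = rep(c("pos", "neg"), each = 20),
    f1 = c(rnorm(20, 5, 0.1), rnorm(20, -5, 0.1))
  )
  suite <- train_suite(tab, seed = 1)
  expect_length(suite$models, 7)
  preds <- predict_suite(suite, tab)
  for (m in suite$models) {
    expect_equal(mean(preds[[m]]$class == tab$label), 1,
                 info = paste("train accuracy of", m))
  }
})

test_that("label-shuffled training yields chance-level held-out accuracy", {
  accs <- vapply(1:20, function(s) {
    tab <- toy_feature_table(20, c("A", "B", "C", "D"), seed = s)
    shuffled <- tab
    shuffled$label <- withr::with_seed(s, sample(tab$label))
    sp <- balanced_split(shuffled, seed = s)
    suite <- train_suite(shuffled[sp$train, ], models = "decision_tree",
                         seed = s)
    rep <- evaluate_suite(suite, shuffled[sp$test, ])
    rep$models$decision_tree$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.25), 0.15)
})

test_that("refitting with the same seed reproduces identical predictions", {
  tab <- toy_feature_table(15, c("A", "B", "C"), noise = 1)
  sp <- balanced_split(tab, seed = 2)
  p1 <- predict_suite(train_suite(tab[sp$train, ], seed = 5), tab[sp$test, ])
  p2 <- predict_suite(train_suite(tab[sp$train, ], seed = 5), tab[sp$test, ])
  for (m in names(p1)) expect_identical(p1[[m]], p2[[m]])
})

test_that("report metrics match hand-tallied values", {
  levels <- c("a", "b", "c")
  truth <- factor(c("a","a","a","b","b","b","c","c","c"), levels = levels)
  pred <- factor(c("a","a","b", "b","b","c", "c","a","c"), levels = levels)
  cm <- occlusignal:::.metrics_one(truth, pred, NULL, levels)
  expect_equal(unclass(cm$confusion),
               matrix(c(2,0,1, 1,2,0, 0,1,2), 3, 3,
                      dimnames = list(levels, levels)),
               ignore_attr = TRUE)
  expect_equal(cm$accuracy, 6 / 9)
  # class a: precision 2/3, recall 2/3, f1 2/3
  expect_equal(cm$per_class$precision[1], 2 / 3)
  expect_equal(cm$per_class$recall[1], 2 / 3)
  expect_equal(cm$per_class$f1[1], 2 / 3)
  expect_equal(cm$macro_f1, 2 / 3)
})

test_that("perfect and inverted predictions bound the metrics", {
  levels <- c("neg", "pos")
  truth <- factor(rep(levels, each = 5), levels = levels)
  scores <- cbind(neg = c(.9,.8,.85,.7,.95,.1,.2,.3,.15,.25),
                  pos = c(.1,.2,.15,.3,.05,.9,.8,.7,.85,.75))
  perfect <- occlusignal:::.metrics_one(truth, truth, scores, levels)
  expect_equal(perfect$accuracy, 1)
  expect_true(all(diag(perfect$confusion) == 5))
  expect_equal(perfect$per_class$auc, c(1, 1))
  inverted <- occlusignal:::.metrics_one(
    truth, factor(rev(truth), levels = levels), scores, levels)
  expect_equal(inverted$accuracy, 0)
  expect_equal(inverted$per_class$auc, c(1, 1))  # scores unchanged
})

test_that("rank-statistic AUC agrees with an independent ROC library", {
  skip_if_not_installed("pROC")
  withr::with_seed(8, {
    scores <- c(rnorm(30, 1), rnorm(40, 0))
    positive <- rep(c(TRUE, FALSE), c(30, 40))
    ours <- rank_auc(scores, positive)
    theirs <- as.numeric(pROC::auc(pROC::roc(positive, scores,
                                             quiet = TRUE,
                                             direction = "<")))
    expect_equal(ours, theirs, tolerance = 1e-12)
  })
  expect_equal(rank_auc(c(3, 2, 1), c(TRUE, TRUE, FALSE)), 1)
  expect_true(is.na(rank_auc(1:3, c(TRUE, TRUE, TRUE))))
})

test_that("permutation importance flags informative sites and not null ones", {
  # AnII vs AnI: the constructed signature lives in the second molars and
  # maxillary incisors
  recs <- simulate_dataset(20, c("AnI", "AnII"), seed = 61)
  cs <- occlusignal:::.derive_seeds(61, length(recs))
  cond <- lapply(seq_along(recs), function(i) {
    condition_recording(recs[[i]], seed = cs[i])
  })
  ft <- suppressWarnings(build_feature_table(cond, aggregate = "per_window"))
  # add a pure-noise feature column as a negative control
  ft$MAX_XXX_abs2 <- withr::with_seed(1, rnorm(nrow(ft)))
  sp <- balanced_split(ft, seed = 1)
  norm <- normalize_features(ft, feature_scaling(ft[sp$train, ]))
  suite <- train_suite(norm[sp$train, ], models = "xgboost", seed = 1)
  imp <- site_importance(suite, norm[sp$test, ], n_repeats = 10, seed = 2)
  overall <- imp[imp$class == "overall", ]
  signature_sites <- c("MAN_LSM", "MAN_RSM", "MAX_LCI", "MAX_RCI",
                       "MAX_LSM", "MAX_RSM", "MAN_LCI", "MAN_RCI")
  top <- overall$site[order(-overall$importance)][1:3]
  expect_gt(length(intersect(top, signature_sites)), 0)
  null_row <- overall[overall$site == "MAX_XXX", ]
  expect_lt(abs(null_row$importance), 2 * max(null_row$se, 0.02))
  expect_error(site_importance(suite, norm[sp$test, ], n_repeats = 1),
               "n_repeats")
  expect_error(site_importance(suite, norm[sp$test, ][1:5, ]), "20")
})

test_that("duplicated feature columns share permutation credit", {
  withr::with_seed(12, {
    tab <- tibble::tibble(
      recording_id = sprintf("r%03d", 1:120),
      label = rep(c("u", "v"), each = 60),
      MAX_LCI_max = c(rnorm(60, 2), rnorm(60, -2)),
      MAX_RCI_max = rnorm(120)
    )
  })
  sp <- balanced_split(tab, seed = 4)
  suite1 <- train_suite(tab[sp$train, ], models = "knn", seed = 1)
  imp1 <- site_importance(suite1, tab[sp$test, ], model = "knn",
                          n_repeats = 10, seed = 3)
  tab2 <- tab
  tab2$MAX_LFP_max <- tab$MAX_LCI_max      # exact duplicate
  suite2 <- train_suite(tab2[sp$train, ], models = "knn", seed = 1)
  imp2 <- site_importance(suite2, tab2[sp$test, ], model = "knn",
                          n_repeats = 10, seed = 3)
  orig <- imp1$importance[imp1$site == "MAX_LCI" & imp1$class == "overall"]
  pair <- sum(imp2$importance[imp2$site %in% c("MAX_LCI", "MAX_LFP") &
                                imp2$class == "overall"])
  # shared credit: the pair's combined importance stays in the same range
  # as the single column's, rather than doubling
  expect_lt(abs(pair - orig), max(0.6 * orig, 0.1))
})

test_that("model failures are isolated and reported, not fatal", {
  tab <- toy_feature_table(10, c("A", "B"))
  suite <- train_suite(tab, seed = 1)
  rep <- evaluate_suite(suite, tab)
  expect_s3_class(glance(rep), "tbl_df")
  expect_true(all(glance(rep)$accuracy >= 0))
  expect_error(train_suite(tab[0, ]), "empty")
  expect_error(evaluate_suite(suite, tab[0, ]))
})
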