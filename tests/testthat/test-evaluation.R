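test_that("metrics reproduce a hand-derived confusion table", {
  labels <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  preds  <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  cc <- confusion_counts(labels, preds)
  expect_equal(cc, c(TP = 3L, FP = 1L, FN = 1L, TN = 5L))
  m <- classification_metrics(labels, preds)
  expect_equal(m[["jaccard"]], 3 / 5)
  expect_equal(m[["dice"]], 6 / 8)
  expect_equal(m[["balanced_accuracy"]], (3 / 4 + 5 / 6) / 2)
  expect_true(is.na(m[["auroc"]]))
  expect_error(confusion_counts(c(1, 0), 1), "equal length")
})

test_that("dice and jaccard satisfy dice = 2J / (1 + J)", {
  set.seed(41)
  for (i in 1:25) {
    lab <- rbinom(40, 1, 0.4)
    pred <- rbinom(40, 1, 0.5)
    m <- suppressWarnings(classification_metrics(lab, pred))
    j <- m[["jaccard"]]
    expect_equal(m[["dice"]], 2 * j / (1 + j), tolerance = 1e-12)
  }
})

test_that("rank AUROC equals the trapezoidal ROC area", {
  set.seed(43)
  for (i in 1:25) {
    lab <- c(rep(1, 12), rep(0, 18))
    sc <- if (i %% 3 == 0) sample(seq(0, 1, 0.1), 30, replace = TRUE) else
      runif(30)                            # with and without ties
    expect_equal(auroc(lab, sc), oracle_auc_trapezoid(lab, sc),
                 tolerance = 1e-12)
  }
  expect_equal(auroc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(auroc(c(1, 1, 0, 0), c(0.1, 0.2, 0.8, 0.9)), 0)
  expect_error(auroc(c(1, 1), c(0.5, 0.6)), "class")
})

test_that("AUROC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(47)
  lab <- rbinom(60, 1, 0.5)
  sc <- rnorm(60) + lab
  ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auroc(lab, sc), ref, tolerance = 1e-12)
})

test_that("the hyperparameter grid has the canonical size and order", {
  g3 <- hqc_grid(3)
  g1 <- hqc_grid(1)
  expect_equal(nrow(g3), 64L)
  expect_equal(nrow(g1), 80L)
  expect_identical(names(g3), c("rescale", "encoding", "copies", "weighting"))
  expect_equal(sort(unique(g3$rescale)), c(0.5, 1, 1.5, 2))
  expect_equal(sort(unique(g3$copies)), 1:4)
  expect_equal(sort(unique(g1$copies)), 1:5)
  # enumeration ascending in (rescale, encoding, copies, weighting)
  key <- order(g3$rescale, g3$encoding, g3$copies, g3$weighting)
  expect_identical(key, seq_len(64L))
  expect_identical(g3[1, ],
                   data.frame(rescale = 0.5, encoding = "amplitude",
                              copies = 1L, weighting = "equiprobable"))
})

test_that("stratified folds balance classes and are reproducible", {
  lab <- rep(c(0L, 1L), c(70, 30))
  f1 <- stratified_folds(lab, k = 5, seed = 3)
  f2 <- stratified_folds(lab, k = 5, seed = 3)
  expect_identical(f1, f2)
  expect_true(all(f1 %in% 1:5))
  per_fold <- table(f1[lab == 1L])
  expect_true(max(per_fold) - min(per_fold) <= 1)
})

test_that("grid search solves a separable problem and is deterministic", {
  tab <- make_separable_table(n = 60, n_features = 1, gap = 6, seed = 1)
  tab <- standardize_features(tab)
  gs <- grid_search(tab, seed = 7)
  expect_s3_class(gs, "hqc_grid_search")
  expect_equal(nrow(gs$results), 80L)
  expect_equal(max(gs$results$mean_score), 1, tolerance = 1e-12)
  expect_equal(evaluate_model(gs, tab)[["balanced_accuracy"]], 1)
  gs2 <- grid_search(tab, seed = 7)
  expect_identical(gs$best, gs2$best)
  expect_equal(gs$results$mean_score, gs2$results$mean_score)
  expect_output(print(gs), "grid search")
  one_class <- tab; one_class$label <- 1L
  expect_error(grid_search(one_class), "both classes")
})

test_that("grid search shrinks the fold count for a rare class", {
  tab <- make_separable_table(n = 60, seed = 2)
  tab <- standardize_features(tab)
  small <- tab[c(which(tab$label == 0), which(tab$label == 1)[1:3]), ]
  expect_warning(gs <- grid_search(small, k = 5, seed = 1), "reducing folds")
  expect_equal(gs$k, 3L)
  tiny <- tab[c(which(tab$label == 0), which(tab$label == 1)[1]), ]
  expect_error(suppressWarnings(grid_search(tiny)), "too few")
})

test_that("the roster lists 18 classifiers, 15 with scores", {
  r <- baseline_roster()
  expect_equal(nrow(r), 18L)
  expect_equal(sum(r$has_scores), 15L)
  expect_identical(sort(r$name[!r$has_scores]),
                   c("nearest_centroid", "passive_aggressive", "perceptron"))
  expect_true(all(c("dummy", "logistic", "svm_rbf", "random_forest",
                    "lda", "qda") %in% r$name))
})

test_that("the comparison harness ranks classifiers on the test objective", {
  tab <- make_separable_table(n = 120, n_features = 2, gap = 4, seed = 5)
  tab <- standardize_features(tab)
  sp <- split_dev_test(tab, 0.8, seed = 6)
  cmp <- suppressWarnings(
    compare_classifiers(sp$development, sp$test, seed = 8))
  expect_true("helstrom_quantum" %in% cmp$classifier)
  expect_identical(names(cmp), c("classifier", "balanced_accuracy", "auroc",
                                 "jaccard", "dice"))
  expect_false(is.unsorted(rev(cmp$balanced_accuracy)))
  # dummy predicts the majority class: balanced accuracy 0.5 on this data
  expect_equal(cmp$balanced_accuracy[cmp$classifier == "dummy"], 0.5)
  # separable data: the Helstrom classifier is at the top score
  expect_equal(cmp$balanced_accuracy[cmp$classifier == "helstrom_quantum"],
               max(cmp$balanced_accuracy))
  # unavailable baselines are absent, with warnings
  expect_false(any(c("adaboost", "perceptron", "passive_aggressive") %in%
                     cmp$classifier))
  expect_warning(compare_classifiers(sp$development, sp$test, seed = 8),
                 "unavailable")
})

test_that("the AUROC comparison drops score-less baselines", {
  tab <- make_separable_table(n = 100, gap = 4, seed = 9)
  tab <- standardize_features(tab)
  sp <- split_dev_test(tab, 0.8, seed = 10)
  cmp <- suppressWarnings(
    compare_classifiers(sp$development, sp$test, objective = "auroc",
                        seed = 11))
  expect_false("nearest_centroid" %in% cmp$classifier)
  expect_false(is.unsorted(rev(cmp$auroc)))
})

test_that("the copies-increment rerun keeps tuned settings but adds a copy", {
  tab <- make_separable_table(n = 80, gap = 3, seed = 12)
  tab <- standardize_features(tab)
  sp <- split_dev_test(tab, 0.8, seed = 13)
  gs <- grid_search(sp$development, seed = 14,
                    grid = hqc_grid(1, copies = 1:2))
  rr <- copies_increment_rerun(gs, sp$development, sp$test)
  hp0 <- rr$original$hyperparameters
  hp1 <- rr$incremented$hyperparameters
  expect_equal(hp1$copies, hp0$copies + 1L)
  expect_equal(hp1$rescale, hp0$rescale)
  expect_equal(hp1$encoding, hp0$encoding)
  expect_equal(hp1$weighting, hp0$weighting)
  expect_true(all(c("balanced_accuracy", "auroc", "jaccard", "dice") %in%
                    names(rr$incremented$metrics)))
  # the cap is honored
  capped <- hqc(as.matrix(sp$development[, "f1", drop = FALSE]),
                sp$development$label, copies = 12L)
  expect_error(copies_increment_rerun(capped, sp$development, sp$test),
               "cap")
})

test_that("extra copies help the fitted separation on average", {
  # On near-separable data, the training-set Helstrom bound with 2 copies
  # is at least the bound with 1 copy (allowing numerical slack), and the
  # test accuracy does not collapse.
  improved <- 0
  for (s in 1:20) {
    tab <- make_separable_table(n = 50, gap = 2.5, seed = 100 + s)
    tab <- standardize_features(tab)
    X <- as.matrix(tab[, "f1", drop = FALSE])
    b1 <- hqc(X, tab$label, copies = 1L, standardize = FALSE)$helstrom_bound
    b2 <- hqc(X, tab$label, copies = 2L, standardize = FALSE)$helstrom_bound
    if (b2 >= b1 - 1e-9) improved <- improved + 1
  }
  expect_equal(improved, 20)
})
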