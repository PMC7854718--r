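#' Confusion counts for binary pixel classification
#'
#' @param labels True binary labels (1 = colony).
#' @param predictions Predicted binary labels.
#' @return Named integer vector `TP`, `FP`, `FN`, `TN`.
#' @export
confusion_counts <- function(labels, predictions) {
  labels <- as.integer(as.numeric(as.character(labels)))
  predictions <- as.integer(as.numeric(as.character(predictions)))
  if (length(labels) != length(predictions)) {
    stop("'labels' and 'predictions' must have equal length", call. = FALSE)
  }
  c(TP = sum(labels == 1L & predictions == 1L),
    FP = sum(labels == 0L & predictions == 1L),
    FN = sum(labels == 1L & predictions == 0L),
    TN = sum(labels == 0L & predictions == 0L))
}

#' Area under the ROC curve (rank statistic)
#'
#' Computed as the normalized Mann-Whitney U statistic with midranks for
#' ties, which equals the trapezoidal area under the empirical ROC curve.
#'
#' @param labels Binary labels (1 = positive).
#' @param scores Numeric scores, larger = more positive.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(labels, scores) {
  labels <- as.integer(as.numeric(as.character(labels)))
  if (length(labels) != length(scores)) {
    stop("'labels' and 'scores' must have equal length", call. = FALSE)
  }
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUROC is undefined when one class is absent", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Classification metrics for colony-vs-background evaluation
#'
#' Balanced accuracy (mean of sensitivity and specificity), Jaccard index
#' `TP / (TP + FP + FN)`, Dice coefficient `2 TP / (2 TP + FP + FN)`, and
#' (when scores are supplied and both classes occur) the AUROC.
#'
#' When one class is absent from `labels`, balanced accuracy degrades to the
#' recall of the present class with a warning and AUROC is `NA`.
#'
#' @param labels True binary labels (1 = colony).
#' @param predictions Predicted binary labels.
#' @param scores Optional numeric scores for the AUROC.
#' @return Named numeric vector `balanced_accuracy`, `auroc`, `jaccard`,
#'   `dice`.
#' @examples
#' classification_metrics(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
#'                        c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0))
#' @export
classification_metrics <- function(labels, predictions, scores = NULL) {
  cc <- confusion_counts(labels, predictions)
  tp <- cc[["TP"]]; fp <- cc[["FP"]]; fn <- cc[["FN"]]; tn <- cc[["TN"]]
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  if (is.na(sens) || is.na(spec)) {
    warning("one class absent: balanced accuracy degrades to recall",
            call. = FALSE)
    ba <- if (is.na(sens)) spec else sens
  } else {
    ba <- (sens + spec) / 2
  }
  jac <- if (tp + fp + fn > 0) tp / (tp + fp + fn) else 1
  dice <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 1
  auc <- NA_real_
  if (!is.null(scores)) {
    lab <- as.integer(as.numeric(as.character(labels)))
    if (sum(lab == 1L) > 0L && sum(lab == 0L) > 0L) {
      auc <- auroc(labels, scores)
    } else {
      warning("one class absent: AUROC undefined", call. = FALSE)
    }
  }
  c(balanced_accuracy = ba, auroc = auc, jaccard = jac, dice = dice)
}

#' Hyperparameter grid for the Helstrom classifier
#'
#' The full factorial grid used in the experiments: rescaling factors
#' `{0.5, 1, 1.5, 2}`, both encodings, copies `{1, 2, 3, 4}` for 3-channel
#' feature sets and `{1, 2, 3, 4, 5}` for scalar descriptors, and both
#' weighting modes -- 64 combinations for 3 features, 80 for 1. Rows are
#' enumerated in ascending lexicographic order of (rescale, encoding,
#' copies, weighting); grid-search ties resolve to the first row.
#'
#' @param n_features Number of features (1 or 3 in the canonical pipeline).
#' @param copies Optional explicit copies set, overriding the default.
#' @return Data frame with columns `rescale`, `encoding`, `copies`,
#'   `weighting`.
#' @export
hqc_grid <- function(n_features, copies = NULL) {
  if (is.null(copies)) copies <- if (n_features >= 2L) 1:4 else 1:5
  g <- expand.grid(weighting = c("equiprobable", "weighted"),
                   copies = as.integer(copies),
                   encoding = c("amplitude", "stereographic"),
                   rescale = c(0.5, 1, 1.5, 2),
                   stringsAsFactors = FALSE)
  # ascending enumeration: rescale, then encoding, copies, weighting
  g <- g[order(g$rescale, g$encoding, g$copies, g$weighting), ]
  rownames(g) <- NULL
  g[, c("rescale", "encoding", "copies", "weighting")]
}

#' Stratified cross-validation folds
#'
#' Assigns each sample to one of `k` folds, stratified by label so every
#' fold receives a near-equal share of each class.
#'
#' @param labels Binary label vector.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(labels, k = 5L, seed = NULL) {
  n <- length(labels)
  folds <- integer(n)
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

fit_score_hqc <- function(train, valid, combo, objective,
                          side_cap = 4096L) {
  feats <- feature_columns(train)
  model <- hqc(as.matrix(train[, feats, drop = FALSE]), train$label,
               rescale = combo$rescale, encoding = combo$encoding,
               copies = combo$copies, weighting = combo$weighting,
               standardize = FALSE, side_cap = side_cap)
  s <- decision_scores(model, as.matrix(valid[, feats, drop = FALSE]))
  pred <- as.integer(s > 0.5)
  m <- suppressWarnings(classification_metrics(valid$label, pred, s))
  m[[objective]]
}

#' Cross-validated grid search for the Helstrom classifier
#'
#' Exhaustive search over the hyperparameter grid with stratified k-fold
#' cross-validation on the development table: the score of a combination is
#' the mean validation objective over the folds, ties resolve to the first
#' combination in enumeration order, and the winner is refitted on the full
#' development set.
#'
#' If a class has fewer members than `k`, the number of folds is reduced to
#' that count (with a warning); below 2 the search stops with an error.
#'
#' @param dev Development pixel table (columns `x`, `y` optional, features,
#'   `label`); the features are assumed already standardized, so the
#'   estimator is fitted with `standardize = FALSE`.
#' @param objective `"balanced_accuracy"` or `"auroc"`.
#' @param k Number of cross-validation folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @param grid Optional explicit grid (defaults to [hqc_grid()] for the
#'   table's feature count).
#' @param side_cap Cap on the encoded matrix side.
#' @return Object of class `"hqc_grid_search"`: list with `results` (the
#'   grid plus `mean_score` per combination), `best` (winning row), `model`
#'   (refit on the full development set) and `objective`.
#' @export
grid_search <- function(dev, objective = c("balanced_accuracy", "auroc"),
                        k = 5L, seed = NULL, grid = NULL,
                        side_cap = 4096L) {
  objective <- match.arg(objective)
  feats <- feature_columns(dev)
  if (length(unique(dev$label)) < 2L) {
    stop("development set must contain both classes", call. = FALSE)
  }
  min_class <- min(table(dev$label))
  if (min_class < k) {
    if (min_class < 2L) {
      stop("too few samples of one class for cross-validation", call. = FALSE)
    }
    warning(sprintf("reducing folds from %d to %d (smallest class size)",
                    k, min_class), call. = FALSE)
    k <- min_class
  }
  if (is.null(grid)) grid <- hqc_grid(length(feats))
  folds <- stratified_folds(dev$label, k = k, seed = seed)
  mean_score <- vapply(seq_len(nrow(grid)), function(i) {
    combo <- grid[i, ]
    sc <- vapply(seq_len(k), function(f) {
      fit_score_hqc(dev[folds != f, , drop = FALSE],
                    dev[folds == f, , drop = FALSE],
                    combo, objective, side_cap)
    }, numeric(1))
    mean(sc, na.rm = TRUE)
  }, numeric(1))
  best_i <- which.max(mean_score)           # first index on ties
  best <- grid[best_i, ]
  model <- hqc(as.matrix(dev[, feats, drop = FALSE]), dev$label,
               rescale = best$rescale, encoding = best$encoding,
               copies = best$copies, weighting = best$weighting,
               standardize = FALSE, side_cap = side_cap)
  structure(list(results = cbind(grid, mean_score = mean_score),
                 best = best, model = model, objective = objective,
                 k = k, seed = seed),
            class = "hqc_grid_search")
}

#' @export
print.hqc_grid_search <- function(x, ...) {
  cat(sprintf("Helstrom classifier grid search (%d combinations, %d-fold CV, objective: %s)\n",
              nrow(x$results), x$k, x$objective))
  b <- x$best
  cat(sprintf("  best: rescale %g, %s encoding, %d cop%s, %s weights (mean score %.4f)\n",
              b$rescale, b$encoding, b$copies,
              if (b$copies == 1) "y" else "ies", b$weighting,
              max(x$results$mean_score)))
  invisible(x)
}

#' Evaluate a fitted model on a test pixel table
#'
#' @param model A fitted `"hqc"` model (or grid-search result).
#' @param test Test pixel table.
#' @return Named metric vector from [classification_metrics()].
#' @export
evaluate_model <- function(model, test) {
  if (inherits(model, "hqc_grid_search")) model <- model$model
  feats <- feature_columns(test)
  s <- decision_scores(model, as.matrix(test[, feats, drop = FALSE]))
  suppressWarnings(classification_metrics(test$label, as.integer(s > 0.5), s))
}

#' Re-run a tuned model with one additional tensor copy
#'
#' The copies-increment protocol: keep the tuned hyperparameters fixed,
#' increment the number of copies by one, refit on the development set, and
#' report the test metrics of both models side by side. This probes the
#' theoretical property that additional state copies can only improve the
#' distinguishability of the two class states.
#'
#' @param search A fitted `"hqc_grid_search"` (or `"hqc"` model).
#' @param dev,test Development and test pixel tables.
#' @param side_cap Cap on the encoded matrix side; exceeding it is an error.
#' @return List with `original` and `incremented`, each holding
#'   `hyperparameters` and `metrics`.
#' @export
copies_increment_rerun <- function(search, dev, test, side_cap = 4096L) {
  model <- if (inherits(search, "hqc_grid_search")) search$model else search
  stopifnot(inherits(model, "hqc"))
  hp <- model$hyperparameters
  feats <- feature_columns(dev)
  side <- (length(feats) + 1L)^(hp$copies + 1L)
  if (side > side_cap) {
    stop(sprintf("incremented copies would need side %d, above cap %d",
                 side, side_cap), call. = FALSE)
  }
  refit <- hqc(as.matrix(dev[, feats, drop = FALSE]), dev$label,
               rescale = hp$rescale, encoding = hp$encoding,
               copies = hp$copies + 1L, weighting = hp$weighting,
               standardize = FALSE, side_cap = side_cap)
  list(original = list(hyperparameters = hp,
                       metrics = evaluate_model(model, test)),
       incremented = list(hyperparameters = refit$hyperparameters,
                          metrics = evaluate_model(refit, test)))
}
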