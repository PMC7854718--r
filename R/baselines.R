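# Baseline classifier registry. Every baseline delegates to an established
# implementation; the harness only adapts inputs/outputs. Each entry's
# fit_predict(train_x, train_y, test_x, params) returns list(pred, scores)
# where pred is a 0/1 vector and scores (P(colony)) may be NULL for
# score-less models. Hyperparameter grids are small conventional grids; the
# comparison is qualitative ranking, not replication of any tuned result.

baseline_registry <- function() {
  as_bin <- function(f) as.integer(as.character(f) == "1")
  yfac <- function(y) factor(y, levels = c(0, 1))

  svm_entry <- function(kernel) {
    list(
      available = function() requireNamespace("e1071", quietly = TRUE),
      has_scores = TRUE,
      grid = lapply(c(0.1, 1, 10), function(cost) list(cost = cost)),
      fit_predict = function(xtr, ytr, xte, params) {
        fit <- e1071::svm(xtr, yfac(ytr), kernel = kernel,
                          cost = params$cost, probability = TRUE)
        pr <- stats::predict(fit, xte, probability = TRUE)
        probs <- attr(pr, "probabilities")
        list(pred = as_bin(pr), scores = probs[, "1"])
      })
  }

  list(
    adaboost = list(available = function() FALSE, has_scores = TRUE,
                    grid = list(list()), fit_predict = NULL),
    bernoulli_nb = list(
      available = function() requireNamespace("e1071", quietly = TRUE),
      has_scores = TRUE,
      grid = list(list()),
      fit_predict = function(xtr, ytr, xte, params) {
        bin <- function(m) as.data.frame(lapply(as.data.frame(m), function(v)
          factor(as.integer(v > 0), levels = 0:1)))
        fit <- e1071::naiveBayes(bin(xtr), yfac(ytr), laplace = 1)
        raw <- stats::predict(fit, bin(xte), type = "raw")
        list(pred = as.integer(raw[, "1"] > 0.5), scores = raw[, "1"])
      }),
    dummy = list(
      available = function() TRUE, has_scores = TRUE,
      grid = list(list()),
      fit_predict = function(xtr, ytr, xte, params) {
        prev <- mean(ytr == 1)
        maj <- as.integer(prev > 0.5)
        list(pred = rep(maj, nrow(xte)), scores = rep(prev, nrow(xte)))
      }),
    extra_trees = list(
      available = function() requireNamespace("ranger", quietly = TRUE),
      has_scores = TRUE,
      grid = list(list(num.trees = 200)),
      fit_predict = function(xtr, ytr, xte, params) {
        df <- data.frame(xtr); df$.y <- yfac(ytr)
        fit <- ranger::ranger(.y ~ ., data = df, probability = TRUE,
                              splitrule = "extratrees",
                              num.trees = params$num.trees,
                              num.random.splits = 1, seed = 1)
        p <- stats::predict(fit, data.frame(xte))$predictions[, "1"]
        list(pred = as.integer(p > 0.5), scores = p)
      }),
    gaussian_nb = list(
      available = function() requireNamespace("e1071", quietly = TRUE),
      has_scores = TRUE,
      grid = list(list()),
      fit_predict = function(xtr, ytr, xte, params) {
        fit <- e1071::naiveBayes(as.data.frame(xtr), yfac(ytr))
        raw <- stats::predict(fit, as.data.frame(xte), type = "raw")
        list(pred = as.integer(raw[, "1"] > 0.5), scores = raw[, "1"])
      }),
    gradient_boosting = list(
      available = function() requireNamespace("xgboost", quietly = TRUE),
      has_scores = TRUE,
      grid = list(list(nrounds = 50, max_depth = 3)),
      fit_predict = function(xtr, ytr, xte, params) {
        fit <- xgboost::xgboost(data = as.matrix(xtr), label = ytr,
                                nrounds = params$nrounds,
                                max_depth = params$max_depth,
                                objective = "binary:logistic",
                                verbose = 0, nthread = 1)
        p <- stats::predict(fit, as.matrix(xte))
        list(pred = as.integer(p > 0.5), scores = p)
      }),
    lda = list(
      available = function() requireNamespace("MASS", quietly = TRUE),
      has_scores = TRUE,
      grid = list(list()),
      fit_predict = function(xtr, ytr, xte, params) {
        fit <- MASS::lda(xtr, yfac(ytr))
        pr <- stats::predict(fit, xte)
        list(pred = as_bin(pr$class), scores = pr$posterior[, "1"])
      }),
    logistic = list(
      available = function() TRUE, has_scores = TRUE,
      grid = list(list()),
      fit_predict = function(xtr, ytr, xte, params) {
        df <- data.frame(xtr); df$.y <- ytr
        fit <- suppressWarnings(stats::glm(.y ~ ., data = df,
                                           family = stats::binomial()))
        p <- stats::predict(fit, data.frame(xte), type = "response")
        list(pred = as.integer(p > 0.5), scores = as.numeric(p))
      }),
    mlp = list(
      available = function() requireNamespace("nnet", quietly = TRUE),
      has_scores = TRUE,
      grid = lapply(c(0.1, 0.01), function(d) list(size = 3, decay = d)),
      fit_predict = function(xtr, ytr, xte, params) {
        fit <- nnet::nnet(xtr, ytr, size = params$size,
                          decay = params$decay, maxit = 200,
                          trace = FALSE, entropy = TRUE)
        p <- as.numeric(stats::predict(fit, xte))
        list(pred = as.integer(p > 0.5), scores = p)
      }),
    nearest_centroid = list(
      available = function() TRUE, has_scores = FALSE,
      grid = list(list()),
      fit_predict = function(xtr, ytr, xte, params) {
        c1 <- colMeans(xtr[ytr == 1, , drop = FALSE])
        c0 <- colMeans(xtr[ytr == 0, , drop = FALSE])
        d1 <- rowSums(sweep(xte, 2, c1)^2)
        d0 <- rowSums(sweep(xte, 2, c0)^2)
        list(pred = as.integer(d1 < d0), scores = NULL)
      }),
    nearest_neighbors = list(
      available = function() requireNamespace("class", quietly = TRUE),
      has_scores = TRUE,
      grid = lapply(c(1, 3, 5), function(k) list(k = k)),
      fit_predict = function(xtr, ytr, xte, params) {
        k <- min(params$k, nrow(xtr))
        pr <- class::knn(xtr, xte, yfac(ytr), k = k, prob = TRUE)
        pwin <- attr(pr, "prob")
        pred <- as_bin(pr)
        list(pred = pred, scores = ifelse(pred == 1L, pwin, 1 - pwin))
      }),
    passive_aggressive = list(available = function() FALSE,
                              has_scores = FALSE,
                              grid = list(list()), fit_predict = NULL),
    perceptron = list(available = function() FALSE, has_scores = FALSE,
                      grid = list(list()), fit_predict = NULL),
    qda = list(
      available = function() requireNamespace("MASS", quietly = TRUE),
      has_scores = TRUE,
      grid = list(list()),
      fit_predict = function(xtr, ytr, xte, params) {
        fit <- MASS::qda(xtr, yfac(ytr))
        pr <- stats::predict(fit, xte)
        list(pred = as_bin(pr$class), scores = pr$posterior[, "1"])
      }),
    random_forest = list(
      available = function() requireNamespace("randomForest", quietly = TRUE),
      has_scores = TRUE,
      grid = list(list(ntree = 200)),
      fit_predict = function(xtr, ytr, xte, params) {
        fit <- randomForest::randomForest(xtr, yfac(ytr),
                                          ntree = params$ntree)
        p <- stats::predict(fit, xte, type = "prob")[, "1"]
        list(pred = as.integer(p > 0.5), scores = p)
      }),
    svm_linear = svm_entry("linear"),
    svm_poly = svm_entry("polynomial"),
    svm_rbf = svm_entry("radial")
  )
}

#' Roster of baseline classifiers
#'
#' The 18 conventional classifiers against which the Helstrom classifier is
#' compared. `has_scores` marks models exposing class probabilities: the
#' three score-less entries (nearest centroid, passive-aggressive,
#' perceptron) are excluded when the objective is AUROC, leaving 15.
#' `available` reflects whether a backing implementation exists in the
#' current R library; unavailable entries are skipped with a warning by
#' [compare_classifiers()].
#'
#' @return Data frame with columns `name`, `available`, `has_scores`.
#' @export
baseline_roster <- function() {
  reg <- baseline_registry()
  data.frame(
    name = names(reg),
    available = vapply(reg, function(e) isTRUE(e$available()), logical(1)),
    has_scores = vapply(reg, function(e) isTRUE(e$has_scores), logical(1)),
    row.names = NULL
  )
}

tune_baseline <- function(entry, dev, objective, k, seed) {
  feats <- feature_columns(dev)
  xd <- as.matrix(dev[, feats, drop = FALSE])
  yd <- dev$label
  grid <- entry$grid
  best_params <- grid[[1L]]
  if (length(grid) > 1L) {
    kk <- min(k, min(table(yd)))
    folds <- stratified_folds(yd, k = kk, seed = seed)
    cvscore <- vapply(grid, function(params) {
      sc <- vapply(seq_len(kk), function(f) {
        tr <- folds != f
        out <- entry$fit_predict(xd[tr, , drop = FALSE], yd[tr],
                                 xd[!tr, , drop = FALSE], params)
        m <- suppressWarnings(
          classification_metrics(yd[!tr], out$pred, out$scores))
        m[[objective]]
      }, numeric(1))
      mean(sc, na.rm = TRUE)
    }, numeric(1))
    best_params <- grid[[which.max(cvscore)]]
  }
  best_params
}

#' Compare the Helstrom classifier against conventional baselines
#'
#' Runs the same tune-on-development / score-on-test protocol for the
#' Helstrom classifier and every available baseline in the roster: small
#' documented hyperparameter grids tuned by stratified k-fold
#' cross-validation, final fit on the full development set, metrics on the
#' test set. For `objective = "auroc"` the score-less baselines are
#' excluded. Baselines whose implementation is unavailable, or that fail on
#' the given data, are skipped with a warning.
#'
#' @param dev,test Development and test pixel tables (standardized).
#' @param objective `"balanced_accuracy"` or `"auroc"`.
#' @param roster Roster data frame (see [baseline_roster()]).
#' @param k Cross-validation folds.
#' @param seed Integer seed.
#' @param side_cap Cap on the Helstrom encoding side.
#' @return Data frame ranked by the test objective, one row per classifier,
#'   with columns `classifier`, `balanced_accuracy`, `auroc`, `jaccard`,
#'   `dice`.
#' @export
compare_classifiers <- function(dev, test,
                                objective = c("balanced_accuracy", "auroc"),
                                roster = baseline_roster(), k = 5L,
                                seed = NULL, side_cap = 4096L) {
  objective <- match.arg(objective)
  reg <- baseline_registry()
  feats <- feature_columns(dev)
  xd <- as.matrix(dev[, feats, drop = FALSE])
  xt <- as.matrix(test[, feats, drop = FALSE])

  gs <- grid_search(dev, objective = objective, k = k, seed = seed,
                    side_cap = side_cap)
  rows <- list(data.frame(classifier = "helstrom_quantum",
                          t(evaluate_model(gs, test))))

  for (i in seq_len(nrow(roster))) {
    nm <- roster$name[i]
    entry <- reg[[nm]]
    if (is.null(entry)) {
      warning(sprintf("unknown roster entry '%s'; skipped", nm),
              call. = FALSE)
      next
    }
    if (objective == "auroc" && !entry$has_scores) next
    if (!entry$available()) {
      warning(sprintf("baseline '%s' unavailable; skipped", nm),
              call. = FALSE)
      next
    }
    res <- tryCatch({
      params <- tune_baseline(entry, dev, objective, k, seed)
      out <- entry$fit_predict(xd, dev$label, xt, params)
      m <- suppressWarnings(
        classification_metrics(test$label, out$pred, out$scores))
      data.frame(classifier = nm, t(m))
    }, error = function(e) {
      warning(sprintf("baseline '%s' failed (%s); skipped", nm,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (!is.null(res)) rows <- c(rows, list(res))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out[[objective]]), ]
  rownames(out) <- NULL
  out
}
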