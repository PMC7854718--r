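# Vectorized encoding of a sample matrix: returns the (n+1)^m x N matrix
# whose j-th column is the m-fold Kronecker power of sample j's amplitude
# vector. Density patterns of single samples are rank-1, so fitting and
# scoring never need to materialize per-sample (n+1)^m square matrices:
# the class centroid is tcrossprod(V)/N and tr(P rho) is a quadratic form.
encode_amplitudes <- function(X, encoding, rescale = 1, copies = 1L,
                              side_cap = 4096L) {
  encoding <- match.arg(encoding, c("amplitude", "stereographic"))
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("features must be finite", call. = FALSE)
  X <- t(rescale_features(X, rescale))          # n x N
  n <- nrow(X)
  side <- (n + 1)^copies
  if (side > side_cap) {
    stop(sprintf(
      "encoding with %d copies of %d features needs side %d, above cap %d",
      copies, n, side, side_cap), call. = FALSE)
  }
  s <- colSums(X^2)
  A <- if (encoding == "stereographic") {
    rbind(2 * X, s - 1) / rep(s + 1, each = n + 1)
  } else {
    rbind(X, 1) / rep(sqrt(s + 1), each = n + 1)
  }
  V <- A
  if (copies > 1L) {
    for (i in seq_len(copies - 1L)) {
      r <- nrow(V)
      V <- V[rep(seq_len(r), each = n + 1L), , drop = FALSE] *
        A[rep(seq_len(n + 1L), times = r), , drop = FALSE]
    }
  }
  V
}

#' Fit the Helstrom quantum classifier
#'
#' Fits a binary classifier inspired by optimal quantum state discrimination.
#' Each standardized, rescaled sample is encoded as a pure quantum state
#' (a rank-1 density pattern), raised to `copies` tensor-product copies, and
#' the two classes are summarized by their quantum centroids (entrywise mean
#' states). The Helstrom observable -- the weighted difference of the two
#' centroids -- is eigendecomposed, and its positive/negative eigenspace
#' projectors define the decision rule: a sample is called positive when
#' `tr(P+ rho_sample) > 0.5`.
#'
#' The four hyperparameters are the rescaling factor, the encoding
#' (`"amplitude"` or `"stereographic"`), the number of tensor copies, and the
#' class weighting (`"equiprobable"` gives both centroids weight 1/2;
#' `"weighted"` uses class proportions).
#'
#' Feature standardization (z-score) is captured at fit time and re-applied
#' to new data at prediction time; set `standardize = FALSE` when the data
#' have already been standardized upstream.
#'
#' @param x Numeric matrix or data frame of features (samples in rows), or a
#'   formula.
#' @param y Binary labels: logical, 0/1 numeric, or a two-level factor. The
#'   second factor level (or the value 1 / `TRUE`) is the positive class.
#' @param rescale Positive rescaling factor applied to the features.
#' @param encoding `"amplitude"` or `"stereographic"`.
#' @param copies Number of tensor-product copies (positive integer).
#' @param weighting `"equiprobable"` or `"weighted"` class weights.
#' @param standardize Capture and apply per-feature z-score standardization.
#' @param side_cap Cap on the encoded matrix side `(n+1)^copies`.
#' @param data Data frame in which to evaluate a formula.
#' @param ... Passed between methods.
#' @return An object of class `"hqc"`: a list with the class centroids,
#'   weights, Helstrom projectors, the Helstrom bound, hyperparameters and
#'   standardization statistics.
#' @seealso [predict.hqc()], [decision_scores()], [helstrom_projectors()]
#' @examples
#' set.seed(1)
#' x <- matrix(c(rnorm(20, -1), rnorm(20, 1)), ncol = 1)
#' y <- rep(c(0, 1), each = 20)
#' fit <- hqc(x, y, copies = 2)
#' fit
#' predict(fit, x[c(1, 40), , drop = FALSE])
#' @export
hqc <- function(x, ...) UseMethod("hqc")

#' @rdname hqc
#' @export
hqc.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  out <- hqc.default(X, y, ...)
  out$call <- match.call()
  out
}

#' @rdname hqc
#' @export
hqc.default <- function(x, y,
                        rescale = 1,
                        encoding = c("amplitude", "stereographic"),
                        copies = 1L,
                        weighting = c("equiprobable", "weighted"),
                        standardize = TRUE,
                        side_cap = 4096L, ...) {
  encoding <- match.arg(encoding)
  weighting <- match.arg(weighting)
  if (!is.numeric(copies) || length(copies) != 1L || copies < 1 ||
      copies != round(copies)) {
    stop("'copies' must be a positive integer", call. = FALSE)
  }
  copies <- as.integer(copies)
  if (!is.numeric(rescale) || length(rescale) != 1L || !is.finite(rescale) ||
      rescale <= 0) {
    stop("'rescale' must be a single positive number", call. = FALSE)
  }
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))

  if (is.factor(y)) {
    if (nlevels(droplevels(y)) > 2L) stop("'y' must be binary", call. = FALSE)
    levs <- levels(y)
    if (length(levs) != 2L) levs <- c(levs, levs)[1:2]
    ybin <- as.integer(y == levs[2L])
  } else {
    ybin <- as.integer(as.logical(y) | (is.numeric(y) & y == 1))
    if (!all(y %in% c(0, 1, TRUE, FALSE))) {
      stop("'y' must be binary (0/1, logical, or two-level factor)",
           call. = FALSE)
    }
    levs <- c("0", "1")
  }
  if (length(ybin) != nrow(X)) stop("length of 'y' must match rows of 'x'",
                                    call. = FALSE)
  n_pos <- sum(ybin == 1L)
  n_neg <- sum(ybin == 0L)
  if (n_pos == 0L) stop("fit error: no samples of the positive class ('",
                        levs[2L], "')", call. = FALSE)
  if (n_neg == 0L) stop("fit error: no samples of the negative class ('",
                        levs[1L], "')", call. = FALSE)

  if (standardize) {
    center <- colMeans(X)
    scale_ <- apply(X, 2, stats::sd)
    scale_[scale_ == 0] <- 1
    Xs <- sweep(sweep(X, 2, center), 2, scale_, "/")
  } else {
    center <- rep(0, ncol(X))
    scale_ <- rep(1, ncol(X))
    Xs <- X
  }

  V <- encode_amplitudes(Xs, encoding, rescale, copies, side_cap)
  Vp <- V[, ybin == 1L, drop = FALSE]
  Vn <- V[, ybin == 0L, drop = FALSE]
  centroid_pos <- tcrossprod(Vp) / n_pos
  centroid_neg <- tcrossprod(Vn) / n_neg

  if (weighting == "equiprobable") {
    w <- c(0.5, 0.5)
  } else {
    w <- c(n_pos, n_neg) / (n_pos + n_neg)
  }
  hp <- helstrom_projectors(centroid_pos, centroid_neg, w[1L], w[2L])

  structure(list(
    centroid_pos = centroid_pos,
    centroid_neg = centroid_neg,
    weight_pos = w[1L],
    weight_neg = w[2L],
    projector_pos = hp$projector_pos,
    projector_neg = hp$projector_neg,
    helstrom_bound = hp$helstrom_bound,
    hyperparameters = list(rescale = rescale, encoding = encoding,
                           copies = copies, weighting = weighting),
    standardization = list(center = center, scale = scale_,
                           applied = standardize),
    levels = levs,
    n_features = ncol(X),
    feature_names = colnames(X),
    side = (ncol(X) + 1L)^copies,
    side_cap = as.integer(side_cap),
    n_train = c(positive = n_pos, negative = n_neg),
    call = match.call()
  ), class = "hqc")
}

#' Decision scores of a fitted Helstrom classifier
#'
#' The score of a sample is `tr(P+ rho)` where `rho` is the sample's encoded
#' density pattern (with copies) and `P+` the positive Helstrom projector.
#' Because `P+ + P- = I` and `tr(rho) = 1`, the positive and negative scores
#' of every sample sum to exactly 1, so the score behaves as a class-1
#' probability-like quantity in `[0, 1]`.
#'
#' @param object A fitted `"hqc"` model.
#' @param newdata Matrix or data frame of features with the same number of
#'   columns used at fit time.
#' @return Numeric vector of scores in `[0, 1]`, one per row of `newdata`.
#' @export
decision_scores <- function(object, newdata) {
  stopifnot(inherits(object, "hqc"))
  X <- as.matrix(newdata)
  if (ncol(X) != object$n_features) {
    stop(sprintf("'newdata' has %d features; model was fitted with %d",
                 ncol(X), object$n_features), call. = FALSE)
  }
  st <- object$standardization
  if (st$applied) X <- sweep(sweep(X, 2, st$center), 2, st$scale, "/")
  hpars <- object$hyperparameters
  V <- encode_amplitudes(X, hpars$encoding, hpars$rescale, hpars$copies,
                         object$side_cap)
  pmin(pmax(colSums(V * (object$projector_pos %*% V)), 0), 1)
}

#' Predict method for Helstrom quantum classifier fits
#'
#' @param object A fitted `"hqc"` model.
#' @param newdata Feature matrix or data frame.
#' @param type `"class"` for predicted labels, `"score"` for the positive
#'   decision score `tr(P+ rho)`.
#' @param ... Unused.
#' @return Labels (as the levels supplied at fit time) or numeric scores.
#'   A score of exactly 0.5 is resolved to the negative (background) class.
#' @export
predict.hqc <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  s <- decision_scores(object, newdata)
  if (type == "score") return(s)
  object$levels[as.integer(s > 0.5) + 1L]
}

#' Hyperparameters of a fitted Helstrom classifier
#'
#' @param object A fitted `"hqc"` model.
#' @return Named list with `rescale`, `encoding`, `copies`, `weighting`.
#' @export
hqc_params <- function(object) {
  stopifnot(inherits(object, "hqc"))
  object$hyperparameters
}

#' @export
print.hqc <- function(x, ...) {
  hp <- x$hyperparameters
  cat("Helstrom quantum classifier\n")
  cat(sprintf("  features: %d, encoded side: %d (%s encoding, %d cop%s)\n",
              x$n_features, x$side, hp$encoding, hp$copies,
              if (hp$copies == 1L) "y" else "ies"))
  cat(sprintf("  rescale: %g, weighting: %s (w+ = %.3f, w- = %.3f)\n",
              hp$rescale, hp$weighting, x$weight_pos, x$weight_neg))
  cat(sprintf("  training samples: %d positive / %d negative\n",
              x$n_train[["positive"]], x$n_train[["negative"]]))
  cat(sprintf("  Helstrom bound: %.4f\n", x$helstrom_bound))
  invisible(x)
}

#' @export
summary.hqc <- function(object, ...) {
  ev <- eigen((object$weight_pos * object$centroid_pos -
                 object$weight_neg * object$centroid_neg +
                 t(object$weight_pos * object$centroid_pos -
                     object$weight_neg * object$centroid_neg)) / 2,
              symmetric = TRUE, only.values = TRUE)$values
  out <- list(model = object,
              observable_eigenvalues = ev,
              rank_pos = sum(ev > 1e-12),
              trace_norm = sum(abs(ev)))
  class(out) <- "summary.hqc"
  out
}

#' @export
print.summary.hqc <- function(x, ...) {
  print(x$model)
  cat(sprintf("  observable trace norm: %.4f; positive eigenspace rank: %d of %d\n",
              x$trace_norm, x$rank_pos, length(x$observable_eigenvalues)))
  ev <- x$observable_eigenvalues
  cat(sprintf("  observable spectrum: [%.4f, %.4f]\n", min(ev), max(ev)))
  invisible(x)
}

#' Save or load a fitted Helstrom classifier as JSON
#'
#' Serializes the full model state (hyperparameters, class weights,
#' centroids, projectors, standardization statistics) to a single JSON file,
#' and restores a model that predicts identically to the original.
#'
#' @param object A fitted `"hqc"` model.
#' @param path File path for the JSON container.
#' @return `write_hqc()` returns `path` invisibly; `read_hqc()` returns an
#'   `"hqc"` object.
#' @export
write_hqc <- function(object, path) {
  stopifnot(inherits(object, "hqc"))
  payload <- unclass(object)
  payload$call <- NULL
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_hqc
#' @export
read_hqc <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("centroid_pos", "centroid_neg", "projector_pos",
              "projector_neg")) {
    p[[f]] <- as.matrix(p[[f]])
  }
  p$hyperparameters$copies <- as.integer(p$hyperparameters$copies)
  p$side <- as.integer(p$side)
  p$side_cap <- as.integer(p$side_cap)
  p$n_train <- unlist(p$n_train)
  p$call <- quote(read_hqc())
  structure(p, class = "hqc")
}
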