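#' Rescale a feature vector or matrix
#'
#' Multiplies every feature value by a positive scalar. Rescaling is one of
#' the four hyperparameters of the Helstrom quantum classifier: although an
#' affine change of scale is irrelevant for most conventional classifiers, it
#' changes where feature vectors land on the encoding hypersphere and can
#' therefore change the distinguishability of the two encoded classes.
#'
#' @param x Numeric vector (one sample) or matrix (samples in rows).
#' @param factor Positive finite scalar.
#' @return `x` with every entry multiplied by `factor`.
#' @examples
#' rescale_features(c(1, 2), 0.5)
#' @export
rescale_features <- function(x, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor <= 0) {
    stop("'factor' must be a single positive finite number", call. = FALSE)
  }
  x * factor
}

check_feature_vector <- function(x) {
  if (!is.numeric(x) || length(x) < 1L || !all(is.finite(x))) {
    stop("feature vector must contain at least one finite numeric entry",
         call. = FALSE)
  }
  invisible(x)
}

#' Stereographic amplitude vector
#'
#' Maps a real n-vector to a unit vector in n+1 dimensions by inverse
#' stereographic projection onto the unit hypersphere:
#' `a = (2 x_1, ..., 2 x_n, ||x||^2 - 1) / (||x||^2 + 1)`.
#' The zero vector lands on the projection pole `(0, ..., 0, -1)`.
#'
#' @param x Numeric feature vector.
#' @return Unit numeric vector of length `length(x) + 1`.
#' @keywords internal
stereographic_amplitude <- function(x) {
  check_feature_vector(x)
  s <- sum(x^2)
  c(2 * x, s - 1) / (s + 1)
}

#' Amplitude-encoding vector
#'
#' Appends the constant 1 to the feature vector and normalizes:
#' `a = (x_1, ..., x_n, 1) / sqrt(||x||^2 + 1)`. The appended component keeps
#' the norm of `x` recoverable from the unit vector, so unlike a bare
#' normalization this encoding does not discard amplitude information.
#'
#' @param x Numeric feature vector.
#' @return Unit numeric vector of length `length(x) + 1`.
#' @keywords internal
amplitude_amplitude <- function(x) {
  check_feature_vector(x)
  c(x, 1) / sqrt(sum(x^2) + 1)
}

#' Encode a feature vector as a density pattern
#'
#' Encodes a real feature vector into a density pattern (density matrix): a
#' symmetric, positive semidefinite, unit-trace matrix representing a pure
#' quantum state. Both encodings first map `x` to a unit amplitude vector
#' `a` in n+1 dimensions and return the rank-1 outer product `a %o% a`.
#'
#' `encode_stereographic()` uses inverse stereographic projection onto the
#' unit hypersphere; `encode_amplitude()` appends a constant component so the
#' vector norm survives normalization.
#'
#' @param x Numeric feature vector with at least one finite entry.
#' @return A `(n+1) x (n+1)` symmetric rank-1 matrix with trace 1.
#' @examples
#' encode_stereographic(c(1, 1))
#' encode_amplitude(c(0, 0))
#' @export
encode_stereographic <- function(x) {
  a <- stereographic_amplitude(x)
  tcrossprod(a)
}

#' @rdname encode_stereographic
#' @export
encode_amplitude <- function(x) {
  a <- amplitude_amplitude(x)
  tcrossprod(a)
}

#' Tensor-product copies of a density pattern
#'
#' Replaces a state `rho` by `rho %x% rho %x% ... %x% rho` (`m` factors).
#' Taking copies of a quantum state can only increase the distinguishability
#' of two states, so the number of copies acts as a capacity hyperparameter
#' of the classifier. The matrix side grows as `side(rho)^m`, which is the
#' complexity driver of the whole method.
#'
#' @param rho Square numeric matrix (a density pattern).
#' @param m Number of copies, a positive integer.
#' @param side_cap Largest admissible side of the result; exceeding it raises
#'   an error rather than attempting an enormous Kronecker product.
#' @return The `m`-fold Kronecker power of `rho`.
#' @examples
#' tensor_copies(diag(c(1, 0)), 2)
#' @export
tensor_copies <- function(rho, m, side_cap = 4096L) {
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m < 1 ||
      m != round(m)) {
    stop("'m' must be a positive integer", call. = FALSE)
  }
  if (!is.matrix(rho) || nrow(rho) != ncol(rho)) {
    stop("'rho' must be a square matrix", call. = FALSE)
  }
  side <- nrow(rho)^m
  if (side > side_cap) {
    stop(sprintf(
      "tensor copies would produce a %d x %d matrix, above the cap of %d",
      side, side, side_cap), call. = FALSE)
  }
  out <- rho
  if (m > 1) for (i in seq_len(m - 1L)) out <- out %x% rho
  out
}

#' Quantum centroid of a set of density patterns
#'
#' The quantum centroid of a class is the arithmetic (entrywise) mean of its
#' density patterns: a convex combination of states, hence itself a valid
#' (generally mixed) state summarizing the class.
#'
#' @param patterns Non-empty list of square numeric matrices of equal side.
#' @return Square matrix of the same side: the entrywise mean.
#' @examples
#' quantum_centroid(list(diag(c(1, 0)), diag(c(0, 1))))
#' @export
quantum_centroid <- function(patterns) {
  if (!is.list(patterns) || length(patterns) == 0L) {
    stop("'patterns' must be a non-empty list of matrices", call. = FALSE)
  }
  sides <- vapply(patterns, function(p) {
    if (!is.matrix(p) || nrow(p) != ncol(p)) {
      stop("every pattern must be a square matrix", call. = FALSE)
    }
    nrow(p)
  }, integer(1))
  if (length(unique(sides)) != 1L) {
    stop("all patterns must have the same side", call. = FALSE)
  }
  Reduce(`+`, patterns) / length(patterns)
}

#' Helstrom observable projectors and discrimination bound
#'
#' Forms the Helstrom observable `Lambda = w+ C+ - w- C-` from the two class
#' centroids and their prior weights, eigendecomposes it, and returns the
#' projectors onto its positive and non-positive eigenspaces together with
#' the Helstrom bound: the maximal probability of correctly discriminating
#' the two states,
#' `w+ tr(P+ C+) + w- tr(P- C-) = (1 + tr|Lambda|) / 2` when `w+ + w- = 1`.
#'
#' Eigendirections with eigenvalue at or below a small numerical floor
#' (`1e-12`) are assigned to the negative projector, so the two projectors
#' always resolve the identity.
#'
#' @param centroid_pos,centroid_neg Symmetric density patterns of equal side.
#' @param weight_pos,weight_neg Non-negative class weights summing to 1.
#' @param sym_tol Tolerance for the symmetry check on the centroids.
#' @return List with elements `projector_pos`, `projector_neg`
#'   (symmetric idempotent matrices summing to the identity) and
#'   `helstrom_bound`.
#' @examples
#' helstrom_projectors(diag(c(1, 0)), diag(c(0, 1)), 0.5, 0.5)
#' @export
helstrom_projectors <- function(centroid_pos, centroid_neg,
                                weight_pos = 0.5, weight_neg = 0.5,
                                sym_tol = 1e-8) {
  if (!is.matrix(centroid_pos) || !is.matrix(centroid_neg) ||
      !all(dim(centroid_pos) == dim(centroid_neg)) ||
      nrow(centroid_pos) != ncol(centroid_pos)) {
    stop("centroids must be square matrices of the same side", call. = FALSE)
  }
  if (max(abs(centroid_pos - t(centroid_pos))) > sym_tol ||
      max(abs(centroid_neg - t(centroid_neg))) > sym_tol) {
    stop("centroids must be symmetric", call. = FALSE)
  }
  if (weight_pos < 0 || weight_neg < 0 ||
      abs(weight_pos + weight_neg - 1) > 1e-10) {
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  }
  lambda <- weight_pos * centroid_pos - weight_neg * centroid_neg
  lambda <- (lambda + t(lambda)) / 2
  es <- eigen(lambda, symmetric = TRUE)
  pos <- es$values > 1e-12
  side <- nrow(lambda)
  if (any(pos)) {
    vp <- es$vectors[, pos, drop = FALSE]
    projector_pos <- tcrossprod(vp)
  } else {
    projector_pos <- matrix(0, side, side)
  }
  projector_neg <- diag(side) - projector_pos
  bound <- weight_pos * sum(projector_pos * centroid_pos) +
    weight_neg * sum(projector_neg * centroid_neg)
  list(projector_pos = projector_pos,
       projector_neg = projector_neg,
       helstrom_bound = bound)
}
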