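# Sum of the w x w neighborhood of every pixel (replicate padding),
# via separable cumulative sums; used for the sFCM spatial term.
box_sum <- function(m, w) {
  half <- (w - 1L) %/% 2L
  if (half == 0L) return(m)
  p <- pad_replicate(m, half)
  cs <- apply(p, 2L, cumsum)
  H <- nrow(m)
  rowsum_ <- cs[(2L * half + 1L):nrow(p), , drop = FALSE] -
    rbind(matrix(0, 1L, ncol(p)),
          cs[seq_len(nrow(p) - 2L * half - 1L), , drop = FALSE])
  cs2 <- t(apply(rowsum_, 1L, cumsum))
  if (nrow(rowsum_) == 1L) cs2 <- matrix(cs2, nrow = 1L)
  out <- cs2[, (2L * half + 1L):ncol(p), drop = FALSE] -
    cbind(matrix(0, H, 1L),
          cs2[, seq_len(ncol(p) - 2L * half - 1L), drop = FALSE])
  out
}

#' Spatial fuzzy c-means segmentation of a feature map
#'
#' Clusters the pixels of a 2-D feature map (typically the local entropy
#' map) with fuzzy c-means, regularized by a spatial term: after each
#' membership update, the membership of pixel `j` in cluster `i` is replaced
#' by `u_ij^p * h_ij^q / sum_k u_kj^p * h_kj^q`, where `h_ij` is the sum of
#' the memberships of cluster `i` over the pixel's spatial neighborhood.
#' With `q = 0` (or a 1 x 1 spatial window) the update is inert and the
#' algorithm reduces to standard FCM.
#'
#' Cluster centers are initialized deterministically at the 25th/75th
#' percentiles of the map (evenly spaced percentiles for `clusters > 2`),
#' so results are reproducible without a seed; `seed` is accepted for
#' interface compatibility and recorded in the result.
#'
#' @param feature_map Numeric matrix (one value per pixel).
#' @param clusters Number of clusters (2 for colony/background).
#' @param fuzzifier Fuzziness exponent `> 1` (default 2).
#' @param spatial_window Odd side of the spatial neighborhood (default 5);
#'   1 disables the spatial term.
#' @param p,q Exponents of the membership and spatial factors.
#' @param max_iter,tol Convergence controls: stop when the largest center
#'   shift falls below `tol` or after `max_iter` sweeps (then the
#'   best-so-far result is returned with `converged = FALSE` and a warning).
#' @param seed Recorded in the output; the default initialization is
#'   deterministic.
#' @return Object of class `"sfcm"`: list with `mask` (binary matrix, 1 =
#'   cluster with the highest center, i.e. colony for an entropy map),
#'   `membership` (pixels x clusters), `centers`, `iterations`, `converged`.
#' @export
sfcm <- function(feature_map, clusters = 2L, fuzzifier = 2,
                 spatial_window = 5L, p = 1, q = 1,
                 max_iter = 100L, tol = 1e-5, seed = NULL) {
  if (fuzzifier <= 1) stop("'fuzzifier' must be > 1", call. = FALSE)
  if (clusters < 2L) stop("'clusters' must be >= 2", call. = FALSE)
  m <- as.matrix(feature_map)
  x <- as.vector(m)
  N <- length(x)
  probs <- seq(0.25, 0.75, length.out = clusters)
  centers <- as.numeric(stats::quantile(x, probs, names = FALSE))
  if (any(duplicated(centers))) {
    centers <- centers + seq_len(clusters) * 1e-9 * max(1, diff(range(x)))
  }
  expo <- 2 / (fuzzifier - 1)
  spatial <- q != 0 && spatial_window > 1L
  u <- NULL
  iterations <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    iterations <- it
    d2 <- outer(x, centers, function(a, b) (a - b)^2)
    d2 <- pmax(d2, 1e-300)
    w <- d2^(-expo / 2)                      # (1/d^2)^(1/(m-1))
    u <- w / rowSums(w)
    if (spatial) {
      h <- vapply(seq_len(clusters), function(k) {
        as.vector(box_sum(matrix(u[, k], nrow(m), ncol(m)), spatial_window))
      }, numeric(N))
      uw <- (u^p) * (h^q)
      u <- uw / rowSums(uw)
    }
    um <- u^fuzzifier
    new_centers <- colSums(um * x) / colSums(um)
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    if (shift < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning(sprintf("sFCM did not converge in %d iterations", max_iter),
            call. = FALSE)
  }
  hard <- max.col(u, ties.method = "first")
  colony_cluster <- which.max(centers)
  mask <- matrix(as.integer(hard == colony_cluster), nrow(m), ncol(m))
  structure(list(mask = mask, membership = u, centers = centers,
                 iterations = iterations, converged = converged,
                 seed = seed),
            class = "sfcm")
}

#' Morphological cleanup of a binary colony mask
#'
#' Applies a morphological opening with a disk structuring element, then
#' removes 8-connected foreground components smaller than `min_area` pixels
#' -- the image-analysis proxy for the biologists' rule of counting only
#' colonies of at least 50 densely-packed cells.
#'
#' @param mask Binary matrix (1 = colony).
#' @param min_area Minimum component area in pixels (default 50).
#' @param opening_radius Disk radius for the opening; 0 skips the opening.
#' @return Binary matrix of the same shape; the output foreground is always
#'   a subset of the opening of the input.
#' @export
postprocess_mask <- function(mask, min_area = 50L, opening_radius = 1L) {
  m <- as.matrix(mask)
  if (!all(m %in% c(0, 1))) stop("'mask' must be binary", call. = FALSE)
  storage.mode(m) <- "integer"
  if (opening_radius > 0L && any(m == 1L)) {
    brush <- EBImage::makeBrush(2L * as.integer(opening_radius) + 1L, "disc")
    m0 <- EBImage::opening(m, brush)
    m <- matrix(as.integer(m0 > 0), nrow(m), ncol(m))
  }
  if (min_area > 0L && any(m == 1L)) {
    lab <- label8_cpp(m)
    areas <- tabulate(lab[lab > 0L])
    keep <- which(areas >= min_area)
    m <- matrix(as.integer(lab %in% keep), nrow(m), ncol(m))
  }
  m
}

#' Ground-truth colony mask of a well image
#'
#' The full ground-truth chain: local entropy map of the luminance (binned
#' over the fixed full intensity scale, as in [feature_stack()]), spatial
#' fuzzy c-means segmentation into colony (high entropy) vs background (low
#' entropy), then morphological cleanup and small-component removal.
#'
#' @param image `H x W x 3` RGB array.
#' @param window Entropy window side.
#' @param levels Gray-level bins for the luminance rebinning.
#' @param min_area,opening_radius Passed to [postprocess_mask()].
#' @param ... Passed to [sfcm()].
#' @return Binary matrix, 1 = colony.
#' @export
ground_truth_mask <- function(image, window = 5L, levels = 256L,
                              min_area = 50L, opening_radius = 1L, ...) {
  g <- gray_from_rgb(image)
  if (max(g) > 1) g <- g / 255
  ent <- entropy_map(rebin_gray(g, levels, range = c(0, 1)),
                     window = window)
  seg <- sfcm(ent, clusters = 2L, ...)
  postprocess_mask(seg$mask, min_area = min_area,
                   opening_radius = opening_radius)
}
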