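#' Rebin an intensity image onto L gray levels
#'
#' Linear histogram rebinning: the intensity range of the image (or a
#' supplied `range`) is mapped affinely onto the integer levels
#' `0 ... L-1`. A constant image maps entirely to level 0.
#'
#' @param image Numeric matrix of intensities.
#' @param levels Number of gray-level bins `L` (at least 2).
#' @param range Optional length-2 intensity range to bin over; defaults to
#'   the image's own min/max.
#' @return Integer matrix with values in `0 ... L-1` and attribute
#'   `"levels"`.
#' @export
rebin_gray <- function(image, levels = 256L, range = NULL) {
  if (!is.numeric(levels) || length(levels) != 1L || levels < 2) {
    stop("'levels' must be an integer >= 2", call. = FALSE)
  }
  levels <- as.integer(levels)
  image <- as.matrix(image)
  if (is.null(range)) range <- base::range(image)
  lo <- range[1L]; hi <- range[2L]
  if (hi <= lo) {
    out <- matrix(0L, nrow(image), ncol(image))
  } else {
    out <- pmin(as.integer(floor((image - lo) / (hi - lo) * levels)),
                levels - 1L)
    out <- pmax(out, 0L)
    dim(out) <- dim(image)
  }
  attr(out, "levels") <- levels
  out
}

#' Gray-level co-occurrence matrix of a window
#'
#' Counts ordered pixel pairs `(p, p + offset)` lying inside the window, by
#' gray level, and normalizes by the total pair count. Accumulation is
#' non-symmetric (the transposed pair is not added); the offset is a
#' `(row, col)` displacement, the default `c(0, 1)` being distance-1
#' horizontal.
#'
#' @param window Integer matrix of gray levels (e.g. from [rebin_gray()]).
#' @param offset Integer `(row, col)` displacement, not both zero.
#' @param levels Number of gray levels; defaults to `max(window) + 1` or the
#'   `"levels"` attribute when present.
#' @return Object of class `"glcm"`: list with `counts` and `normalized`
#'   (L x L matrices), `offset` and `levels`. If the window admits no pair at
#'   this offset both matrices are all zero.
#' @examples
#' g <- glcm(matrix(c(0L, 0L, 1L, 1L), 2, 2), offset = c(0, 1), levels = 2)
#' g$normalized
#' @export
glcm <- function(window, offset = c(0L, 1L), levels = NULL) {
  window <- as.matrix(window)
  if (length(window) == 0L) stop("'window' must be non-empty", call. = FALSE)
  offset <- as.integer(offset)
  if (length(offset) != 2L || all(offset == 0L)) {
    stop("'offset' must be a nonzero (row, col) displacement", call. = FALSE)
  }
  if (is.null(levels)) {
    levels <- attr(window, "levels")
    if (is.null(levels)) levels <- max(window) + 1L
  }
  levels <- as.integer(levels)
  H <- nrow(window); W <- ncol(window)
  dr <- offset[1L]; dc <- offset[2L]
  rows <- seq_len(H); cols <- seq_len(W)
  r1 <- rows[rows + dr >= 1L & rows + dr <= H]
  c1 <- cols[cols + dc >= 1L & cols + dc <= W]
  counts <- matrix(0, levels, levels)
  if (length(r1) > 0L && length(c1) > 0L) {
    i <- as.vector(window[r1, c1, drop = FALSE])
    j <- as.vector(window[r1 + dr, c1 + dc, drop = FALSE])
    tab <- table(factor(i, levels = 0:(levels - 1L)),
                 factor(j, levels = 0:(levels - 1L)))
    counts <- matrix(as.numeric(tab), levels, levels)
  }
  total <- sum(counts)
  normalized <- if (total > 0) counts / total else counts
  structure(list(counts = counts, normalized = normalized,
                 offset = offset, levels = levels),
            class = "glcm")
}

#' Haralick descriptors of a GLCM
#'
#' Computes the four texture descriptors from a normalized co-occurrence
#' matrix `p(i, j)` over levels `i, j = 0 ... L-1`:
#' contrast `sum (i-j)^2 p`, correlation
#' `sum (i - mu_i)(j - mu_j) p / (sigma_i sigma_j)`, energy `sum p^2`
#' (angular second moment), and homogeneity `sum p / (1 + |i-j|)`.
#' When either marginal variance is zero the correlation is undefined and is
#' reported as 0.
#'
#' @param g A `"glcm"` object or a normalized L x L matrix.
#' @return Named numeric vector `contrast`, `correlation`, `energy`,
#'   `homogeneity`.
#' @export
haralick_features <- function(g) {
  p <- if (inherits(g, "glcm")) g$normalized else as.matrix(g)
  L <- nrow(p)
  if (sum(p) == 0) {
    return(c(contrast = 0, correlation = 0, energy = 0, homogeneity = 0))
  }
  lev <- 0:(L - 1L)
  I <- matrix(lev, L, L)
  J <- t(I)
  pi_ <- rowSums(p); pj_ <- colSums(p)
  mi <- sum(lev * pi_); mj <- sum(lev * pj_)
  vi <- sum((lev - mi)^2 * pi_); vj <- sum((lev - mj)^2 * pj_)
  corr <- if (vi <= 0 || vj <= 0) 0 else
    sum((I - mi) * (J - mj) * p) / sqrt(vi * vj)
  c(contrast = sum((I - J)^2 * p),
    correlation = corr,
    energy = sum(p^2),
    homogeneity = sum(p / (1 + abs(I - J))))
}

pad_replicate <- function(m, half) {
  if (half == 0L) return(m)
  ri <- c(rep(1L, half), seq_len(nrow(m)), rep(nrow(m), half))
  ci <- c(rep(1L, half), seq_len(ncol(m)), rep(ncol(m), half))
  m[ri, ci, drop = FALSE]
}

check_window <- function(window) {
  if (!is.numeric(window) || length(window) != 1L || window < 3 ||
      window %% 2 == 0) {
    stop("'window' must be an odd integer >= 3", call. = FALSE)
  }
  as.integer(window)
}

#' Sliding-window GLCM descriptor maps
#'
#' For every pixel, computes the four Haralick descriptors of the
#' co-occurrence matrix of its `window x window` neighborhood (replicate
#' padding at the borders, so the maps keep the image shape).
#'
#' @param gray Integer gray-level matrix (see [rebin_gray()]).
#' @param window Odd window side (default 5).
#' @param offset Co-occurrence displacement, default `c(0, 1)`.
#' @return Named list of four numeric matrices (`contrast`, `correlation`,
#'   `energy`, `homogeneity`) with the shape of `gray`. One warning is
#'   emitted per image if any window had zero marginal variance (its
#'   correlation is reported as 0).
#' @export
texture_maps <- function(gray, window = 5L, offset = c(0L, 1L)) {
  window <- check_window(window)
  offset <- as.integer(offset)
  if (length(offset) != 2L || all(offset == 0L)) {
    stop("'offset' must be a nonzero (row, col) displacement", call. = FALSE)
  }
  g <- as.matrix(gray)
  storage.mode(g) <- "integer"
  half <- (window - 1L) %/% 2L
  padded <- pad_replicate(g, half)
  res <- glcm_maps_cpp(padded, window, offset[1L], offset[2L])
  if (isTRUE(res$zero_variance_seen)) {
    warning("zero-variance window(s): correlation reported as 0 there",
            call. = FALSE)
  }
  res$zero_variance_seen <- NULL
  lapply(res, function(m) { dim(m) <- dim(g); m })
}

#' Local Shannon entropy map
#'
#' Per pixel, the entropy (in bits) of the gray-level histogram of the
#' `window x window` neighborhood, with replicate padding. Ranges from 0
#' (constant window) to `log2(min(L, window^2))`.
#'
#' @inheritParams texture_maps
#' @return Numeric matrix with the shape of `gray`.
#' @export
entropy_map <- function(gray, window = 5L) {
  window <- check_window(window)
  g <- as.matrix(gray)
  storage.mode(g) <- "integer"
  half <- (window - 1L) %/% 2L
  out <- entropy_map_cpp(pad_replicate(g, half), window)
  dim(out) <- dim(g)
  out
}

#' Convert an sRGB image to CIE L*u*v*
#'
#' Standard CIE 1976 L*u*v* conversion under the D65 white point, applying
#' the sRGB transfer function first. Accepts an `H x W x 3` array with
#' values either in `[0, 1]` or 8-bit `[0, 255]` (detected from the data
#' maximum).
#'
#' @param image `H x W x 3` numeric array (R, G, B).
#' @return `H x W x 3` array with channels L*, u*, v* (L* in `[0, 100]`).
#' @export
rgb_to_luv <- function(image) {
  d <- dim(image)
  if (length(d) != 3L || d[3L] != 3L) {
    stop("'image' must be an H x W x 3 RGB array", call. = FALSE)
  }
  rgb <- matrix(as.numeric(image), ncol = 3L)
  if (max(rgb) > 1) rgb <- rgb / 255
  # sRGB electro-optical transfer
  lin <- ifelse(rgb <= 0.04045, rgb / 12.92, ((rgb + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- lin %*% t(M)
  Xn <- 0.950456; Yn <- 1; Zn <- 1.088754   # D65
  yr <- xyz[, 2L] / Yn
  Lst <- ifelse(yr > (6 / 29)^3, 116 * yr^(1 / 3) - 16, (29 / 3)^3 * yr)
  denom <- xyz[, 1L] + 15 * xyz[, 2L] + 3 * xyz[, 3L]
  up <- ifelse(denom > 0, 4 * xyz[, 1L] / denom, 0)
  vp <- ifelse(denom > 0, 9 * xyz[, 2L] / denom, 0)
  dn <- Xn + 15 * Yn + 3 * Zn
  upn <- 4 * Xn / dn; vpn <- 9 * Yn / dn
  ust <- 13 * Lst * (up - upn)
  vst <- 13 * Lst * (vp - vpn)
  out <- array(c(Lst, ust, vst), dim = c(d[1L], d[2L], 3L))
  dimnames(out) <- list(NULL, NULL, c("L", "u", "v"))
  out
}

#' Luminance of an RGB image
#'
#' ITU-R BT.601 weighted sum `0.299 R + 0.587 G + 0.114 B`, the gray-level
#' source used for the co-occurrence and entropy maps.
#'
#' @param image `H x W x 3` numeric array.
#' @return Numeric matrix of luminances on the scale of the input channels.
#' @export
gray_from_rgb <- function(image) {
  d <- dim(image)
  if (length(d) != 3L || d[3L] != 3L) {
    stop("'image' must be an H x W x 3 RGB array", call. = FALSE)
  }
  0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L]
}

#' Full per-pixel feature stack of a well-plate image
#'
#' Computes all per-pixel descriptor maps used in colony-vs-background
#' classification: the raw R, G, B channels, the CIE L*u*v* conversion, the
#' four GLCM texture descriptors of the rebinned luminance, and the local
#' entropy map (used for ground-truth segmentation).
#'
#' The gray levels for the co-occurrence and entropy maps are the luminance
#' rebinned over the fixed full intensity scale (for 8-bit data and the
#' default `levels = 256` this is identity binning), not over the image's
#' own min-max range: a low-contrast image must not have its background
#' noise stretched across all bins.
#'
#' @param image `H x W x 3` RGB array (values in `[0, 1]` or `[0, 255]`).
#' @param window Sliding-window side for the texture and entropy maps.
#' @param levels Number of gray-level bins for the rebinned luminance.
#' @param offset Co-occurrence displacement.
#' @return Named list of 11 matrices: `R`, `G`, `B`, `L`, `u`, `v`,
#'   `contrast`, `correlation`, `energy`, `homogeneity`, `entropy`, plus
#'   attributes `window`, `levels`.
#' @export
feature_stack <- function(image, window = 5L, levels = 256L,
                          offset = c(0L, 1L)) {
  d <- dim(image)
  if (length(d) != 3L || d[3L] != 3L) {
    stop("'image' must be an H x W x 3 RGB array", call. = FALSE)
  }
  luv <- rgb_to_luv(image)
  g <- gray_from_rgb(image)
  if (max(g) > 1) g <- g / 255
  gray <- rebin_gray(g, levels, range = c(0, 1))
  tex <- texture_maps(gray, window = window, offset = offset)
  out <- list(R = image[, , 1L], G = image[, , 2L], B = image[, , 3L],
              L = luv[, , 1L], u = luv[, , 2L], v = luv[, , 3L],
              contrast = tex$contrast, correlation = tex$correlation,
              energy = tex$energy, homogeneity = tex$homogeneity,
              entropy = entropy_map(gray, window = window))
  attr(out, "window") <- as.integer(window)
  attr(out, "levels") <- as.integer(levels)
  out
}

#' Feature-set column selection
#'
#' Maps a feature-set name to the columns of the feature stack it uses:
#' the two color encodings are 3-channel sets, the four texture descriptors
#' are scalar sets.
#'
#' @param feature_set One of `"rgb"`, `"luv"`, `"contrast"`,
#'   `"correlation"`, `"energy"`, `"homogeneity"`.
#' @return Character vector of feature-stack map names.
#' @export
feature_set_maps <- function(feature_set) {
  feature_set <- match.arg(feature_set,
                           c("rgb", "luv", "contrast", "correlation",
                             "energy", "homogeneity"))
  switch(feature_set,
         rgb = c("R", "G", "B"),
         luv = c("L", "u", "v"),
         feature_set)
}
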