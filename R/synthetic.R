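#' Specification of a synthetic well-plate crop
#'
#' Parameters of one synthetic 6-well-plate crop: a square interior region
#' of a crystal-violet-stained well, with textured colonies on a smooth
#' stained-plate background. Compactness controls both the sharpness of the
#' colony edge (1 = compact disc with a crisp boundary, low values = diffuse
#' "evanescent" colonies with wide soft fringes) and the strength of the
#' intra-colony speckle.
#'
#' @param side Image side in pixels (default 301, at least 64).
#' @param n_colonies Number of colonies.
#' @param radius_mean,radius_sd Colony radius distribution in pixels
#'   (truncated at 3 px).
#' @param contrast Peak colony signal in `(0, 1]` (how much dye the colonies
#'   take up relative to the plate).
#' @param compactness Edge sharpness/uniformity in `(0, 1]`.
#' @param background_sd Standard deviation of the background texture noise.
#' @param stain_color,colony_color RGB triplets in `[0, 1]` of the stained
#'   plate and of a fully stained colony.
#' @param allow_overlap Place colonies without the minimum-distance retry
#'   loop (colonies merging is a real phenomenon in fast-growing lines).
#' @param seed Master seed; geometry and noise use separate sub-streams
#'   derived from it.
#' @return List of class `"well_spec"`.
#' @export
well_spec <- function(side = 301L, n_colonies = 10L,
                      radius_mean = 12, radius_sd = 3,
                      contrast = 0.8, compactness = 0.9,
                      background_sd = 0.005,
                      stain_color = c(0.85, 0.82, 0.88),
                      colony_color = c(0.45, 0.25, 0.55),
                      allow_overlap = FALSE, seed = 1L) {
  if (side < 64L) stop("'side' must be at least 64", call. = FALSE)
  if (contrast <= 0 || contrast > 1) stop("'contrast' must be in (0, 1]",
                                          call. = FALSE)
  if (compactness <= 0 || compactness > 1) {
    stop("'compactness' must be in (0, 1]", call. = FALSE)
  }
  structure(list(side = as.integer(side), n_colonies = as.integer(n_colonies),
                 radius_mean = radius_mean, radius_sd = radius_sd,
                 contrast = contrast, compactness = compactness,
                 background_sd = background_sd, stain_color = stain_color,
                 colony_color = colony_color,
                 allow_overlap = isTRUE(allow_overlap),
                 seed = as.integer(seed)),
            class = "well_spec")
}

smoothstep <- function(s) {
  s <- pmin(pmax(s, 0), 1)
  s * s * (3 - 2 * s)
}

#' Generate a synthetic well image with its ground-truth mask
#'
#' Renders the well described by a [well_spec()]: colonies are
#' radial-falloff blobs (smoothstep edge whose width grows as compactness
#' drops) carrying multiplicative speckle, composited over a
#' stained-plate background with mild Gaussian texture; the image is
#' quantized to 8 bits per channel as a flat-bed scanner would produce.
#'
#' The mask marks pixels where the noise-free colony signal exceeds half its
#' peak, so it depends only on the geometry sub-stream: regenerating with a
#' different `noise_seed` changes the image but not the mask.
#'
#' @param spec A `"well_spec"`.
#' @param noise_seed Optional override of the noise sub-stream seed.
#' @return List with `image` (`side x side x 3` array in `[0, 1]`), `mask`
#'   (binary matrix) and `spec`.
#' @export
generate_well <- function(spec, noise_seed = NULL) {
  stopifnot(inherits(spec, "well_spec"))
  side <- spec$side
  seeds <- with_seed(spec$seed, sample.int(.Machine$integer.max - 1L, 2L))
  geom_seed <- seeds[1L]
  if (is.null(noise_seed)) noise_seed <- seeds[2L]

  # --- geometry stream: centers and radii ---------------------------------
  ctr <- (side + 1) / 2
  well_radius <- 0.47 * side
  geom <- with_seed(geom_seed, {
    n <- spec$n_colonies
    radii <- numeric(0); cx <- numeric(0); cy <- numeric(0)
    overlap_warned <- FALSE
    if (n > 0L) {
      radii <- pmax(stats::rnorm(n, spec$radius_mean, spec$radius_sd), 3)
      radii <- pmin(radii, well_radius * 0.9)
      for (i in seq_len(n)) {
        placed <- FALSE
        for (try in seq_len(40L)) {
          rr <- (well_radius - radii[i]) * sqrt(stats::runif(1))
          th <- stats::runif(1, 0, 2 * pi)
          px <- ctr + rr * cos(th); py <- ctr + rr * sin(th)
          ok <- spec$allow_overlap || i == 1L ||
            all(sqrt((px - cx)^2 + (py - cy)^2) >
                  0.8 * (radii[i] + radii[seq_len(i - 1L)]))
          if (ok) { cx[i] <- px; cy[i] <- py; placed <- TRUE; break }
        }
        if (!placed) {
          if (!overlap_warned && !spec$allow_overlap) {
            warning("could not place all colonies without overlap; allowing merges",
                    call. = FALSE)
            overlap_warned <- TRUE
          }
          cx[i] <- px; cy[i] <- py
        }
      }
    }
    list(cx = cx, cy = cy, radii = radii)
  })

  # --- noise-free colony signal and mask ----------------------------------
  xs <- matrix(rep(seq_len(side), each = side), side, side)   # column index
  ys <- matrix(rep(seq_len(side), times = side), side, side)  # row index
  signal <- matrix(0, side, side)
  for (i in seq_along(geom$radii)) {
    R <- geom$radii[i]
    edge <- R * (1 - spec$compactness) + 0.75
    r <- sqrt((xs - geom$cx[i])^2 + (ys - geom$cy[i])^2)
    signal <- signal + smoothstep((R - r) / edge)
  }
  signal <- pmin(signal, 1) * spec$contrast
  mask <- matrix(as.integer(signal > spec$contrast / 2), side, side)

  # --- noise stream: speckle and background texture -----------------------
  img <- with_seed(noise_seed, {
    speckle_sd <- 0.1 + 0.15 * (1 - spec$compactness)
    s_noisy <- signal * (1 + stats::rnorm(side * side, sd = speckle_sd))
    s_noisy <- pmin(pmax(s_noisy, 0), 1)
    texture <- stats::rnorm(side * side, sd = spec$background_sd)
    out <- array(0, dim = c(side, side, 3L))
    for (k in 1:3) {
      ch <- spec$stain_color[k] +
        s_noisy * (spec$colony_color[k] - spec$stain_color[k]) + texture
      out[, , k] <- matrix(pmin(pmax(ch, 0), 1), side, side)
    }
    round(out * 255) / 255
  })

  list(image = img, mask = mask, spec = spec)
}

regime_parameters <- function(regime) {
  # Coverage targets: the downstream protocol samples 181 pixels per well,
  # so the main regimes aim at roughly 8-15% colony coverage (tens of
  # colony pixels per sample); background_sd models flat-bed scanner noise
  # of about one 8-bit quantization step.
  switch(regime,
    compact = list(n = 10:16, radius = c(14, 20), radius_sd = 2,
                   contrast = c(0.7, 0.9), compactness = c(0.85, 0.95),
                   background_sd = 0.005, allow_overlap = FALSE),
    evanescent = list(n = 6:12, radius = c(18, 26), radius_sd = 3,
                      contrast = c(0.18, 0.3), compactness = c(0.25, 0.4),
                      background_sd = 0.005, allow_overlap = FALSE),
    large_merging = list(n = 5:9, radius = c(28, 40), radius_sd = 4,
                         contrast = c(0.6, 0.8), compactness = c(0.7, 0.8),
                         background_sd = 0.005, allow_overlap = TRUE),
    small_sparse = list(n = 6:10, radius = c(6, 9), radius_sd = 1.5,
                        contrast = c(0.75, 0.9), compactness = c(0.85, 0.95),
                        background_sd = 0.005, allow_overlap = FALSE))
}

#' Generate a suite of synthetic wells for one cell-line regime
#'
#' Draws `n_wells` wells from regime-specific parameter distributions. The
#' four regimes emulate the qualitative difficulty ordering of the cell
#' lines studied in clonogenic assays: `"compact"` (small, high-contrast,
#' well-bounded colonies -- easy), `"small_sparse"` (few small crisp
#' colonies), `"large_merging"` (large colonies that merge), and
#' `"evanescent"` (large, diffuse, low-contrast colonies that take up little
#' dye -- hard).
#'
#' @param regime One of `"compact"`, `"evanescent"`, `"large_merging"`,
#'   `"small_sparse"`.
#' @param n_wells Number of wells (default 30, the per-line count of the
#'   canonical experiment).
#' @param seed Master seed; each well gets an independent sub-seed.
#' @param side Image side in pixels.
#' @return List of `n_wells` elements, each as returned by
#'   [generate_well()].
#' @export
generate_cell_line_suite <- function(regime = c("compact", "evanescent",
                                                "large_merging",
                                                "small_sparse"),
                                     n_wells = 30L, seed = 1L, side = 301L) {
  regime <- match.arg(regime)
  if (n_wells < 1L) stop("'n_wells' must be >= 1", call. = FALSE)
  par <- regime_parameters(regime)
  draws <- with_seed(seed, {
    lapply(seq_len(n_wells), function(i) list(
      n = sample(par$n, 1L),
      radius = stats::runif(1, par$radius[1L], par$radius[2L]),
      contrast = stats::runif(1, par$contrast[1L], par$contrast[2L]),
      compactness = stats::runif(1, par$compactness[1L],
                                 par$compactness[2L]),
      seed = sample.int(.Machine$integer.max - 1L, 1L)))
  })
  lapply(draws, function(d) {
    generate_well(well_spec(
      side = side, n_colonies = d$n, radius_mean = d$radius,
      radius_sd = par$radius_sd, contrast = d$contrast,
      compactness = d$compactness, background_sd = par$background_sd,
      allow_overlap = par$allow_overlap, seed = d$seed))
  })
}

#' Pixel-level linear separability probe
#'
#' A fixed, deliberately simple classifier used only to compare regimes: it
#' samples pixels from each class, thresholds the luminance at the midpoint
#' of the two class means, and reports the balanced accuracy. Higher values
#' mean the colony pixels are more linearly separable from the background.
#'
#' @param image RGB array.
#' @param mask Binary ground-truth mask.
#' @param n_per_class Pixels sampled per class.
#' @param seed Integer seed.
#' @return Balanced accuracy of the midpoint-threshold rule in `[0, 1]`.
#' @export
probe_separability <- function(image, mask, n_per_class = 500L, seed = 1L) {
  g <- gray_from_rgb(image)
  pos <- which(mask == 1L); neg <- which(mask == 0L)
  if (length(pos) == 0L || length(neg) == 0L) return(0.5)
  idx <- with_seed(seed, list(
    pos = sample(pos, min(n_per_class, length(pos))),
    neg = sample(neg, min(n_per_class, length(neg)))))
  mp <- mean(g[idx$pos]); mn <- mean(g[idx$neg])
  thr <- (mp + mn) / 2
  dir <- if (mp < mn) `<` else `>`
  sens <- mean(dir(g[idx$pos], thr))
  spec <- mean(!dir(g[idx$neg], thr))
  (sens + spec) / 2
}

#' Write a synthetic well to disk
#'
#' Writes `<name>.png` (the image), `<name>_mask.png` (the 0/255 mask) and
#' `<name>.json` (the spec) into `dir`.
#'
#' @param well As returned by [generate_well()].
#' @param dir Output directory (created if missing).
#' @param name File stem.
#' @return Invisibly, the three paths.
#' @export
write_well <- function(well, dir, name = "well") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p_img <- file.path(dir, paste0(name, ".png"))
  p_mask <- file.path(dir, paste0(name, "_mask.png"))
  p_json <- file.path(dir, paste0(name, ".json"))
  png::writePNG(well$image, p_img)
  png::writePNG(well$mask + 0, p_mask)
  jsonlite::write_json(unclass(well$spec), p_json, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(image = p_img, mask = p_mask, spec = p_json))
}

#' Read a well image (and optional mask) from PNG
#'
#' @param image_path PNG path of the RGB image.
#' @param mask_path Optional PNG path of a binary mask.
#' @return List with `image` (H x W x 3 array) and `mask` (binary matrix or
#'   `NULL`).
#' @export
read_well <- function(image_path, mask_path = NULL) {
  img <- png::readPNG(image_path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3L] > 3L) img <- img[, , 1:3]
  mask <- NULL
  if (!is.null(mask_path)) {
    m <- png::readPNG(mask_path)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    mask <- matrix(as.integer(m > 0.5), nrow(m), ncol(m))
  }
  list(image = img, mask = mask)
}
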