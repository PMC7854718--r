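# Evaluate `code` under a temporary RNG seed, restoring the caller's
# RNG state afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  code
}

round_half_up <- function(x) floor(x + 0.5)

feature_columns <- function(table) {
  setdiff(names(table), c("x", "y", "label"))
}

#' Serialize feature maps and a mask into a pixel table
#'
#' Flattens per-pixel feature maps and a binary label mask into one row per
#' pixel, in row-major order (all pixels of the first image row, then the
#' second, ...). Column order is fixed: `x` and `y` (0-based column and row
#' coordinates) first, the features in the middle, and the binary `label`
#' last.
#'
#' @param maps Named list of numeric matrices of one common shape, or a
#'   single matrix.
#' @param mask Binary matrix of the same shape (1 = colony).
#' @return Data frame with `2 + length(maps) + 1` columns and one row per
#'   pixel.
#' @export
serialize_pixels <- function(maps, mask) {
  if (is.matrix(maps)) maps <- list(feature = maps)
  if (length(maps) == 0L) stop("'maps' must contain at least one map",
                               call. = FALSE)
  if (is.null(names(maps)) || any(names(maps) == "")) {
    names(maps) <- paste0("f", seq_along(maps))
  }
  dm <- dim(maps[[1L]])
  ok <- vapply(maps, function(m) identical(dim(m), dm), logical(1))
  if (!all(ok) || !identical(dim(as.matrix(mask)), dm)) {
    stop("all maps and the mask must share one shape", call. = FALSE)
  }
  mask <- as.matrix(mask)
  if (!all(mask %in% c(0, 1))) stop("'mask' must be binary", call. = FALSE)
  H <- dm[1L]; W <- dm[2L]
  out <- data.frame(
    x = rep(0:(W - 1L), times = H),
    y = rep(0:(H - 1L), each = W)
  )
  for (nm in names(maps)) out[[nm]] <- as.vector(t(maps[[nm]]))
  out$label <- as.integer(as.vector(t(mask)))
  out
}

#' Rebuild the label mask from a full pixel table
#'
#' Inverse of the label part of [serialize_pixels()] for an unsampled table.
#'
#' @param table Pixel table covering every pixel exactly once.
#' @return Binary matrix.
#' @export
mask_from_table <- function(table) {
  H <- max(table$y) + 1L
  W <- max(table$x) + 1L
  m <- matrix(0L, H, W)
  m[cbind(table$y + 1L, table$x + 1L)] <- as.integer(table$label)
  m
}

#' Normalize feature columns to the range [1, 255]
#'
#' Per feature, an affine map sends the observed minimum to `lower` and the
#' observed maximum to `upper`. A constant feature is mapped to `lower` with
#' a warning.
#'
#' @param table Pixel table (data frame with `x`, `y`, features, `label`).
#' @param lower,upper Target range endpoints (defaults 1 and 255).
#' @return The table with feature columns rescaled.
#' @export
normalize_range <- function(table, lower = 1, upper = 255) {
  if (nrow(table) < 1L) stop("table must have at least one row", call. = FALSE)
  for (f in feature_columns(table)) {
    v <- table[[f]]
    rng <- range(v)
    if (rng[2L] > rng[1L]) {
      table[[f]] <- lower + (v - rng[1L]) / (rng[2L] - rng[1L]) *
        (upper - lower)
    } else {
      warning(sprintf("feature '%s' is constant; set to %g", f, lower),
              call. = FALSE)
      table[[f]] <- rep(lower, length(v))
    }
  }
  table
}

#' Random pixel sample of a table
#'
#' Uniform sampling without replacement of `fraction` of the rows (rounded
#' half away from zero, so the canonical 0.2% sample of a 301 x 301 image is
#' 181 of 90601 rows). Reproducible under `seed`.
#'
#' @param table Pixel table.
#' @param fraction Sampling fraction in `(0, 1]`.
#' @param seed Integer seed.
#' @return The sampled table (row order randomized).
#' @export
sample_pixels <- function(table, fraction = 0.002, seed = NULL) {
  if (fraction <= 0 || fraction > 1) {
    stop("'fraction' must be in (0, 1]", call. = FALSE)
  }
  n <- round_half_up(fraction * nrow(table))
  if (n < 1) stop("sample would be empty", call. = FALSE)
  idx <- with_seed(seed, sample.int(nrow(table), n))
  table[idx, , drop = FALSE]
}

#' Z-score standardization of feature columns
#'
#' Per feature, subtracts the mean and divides by the standard deviation.
#' The population convention (divide by n) is the default; stats are
#' attached to the result (attribute `"standardization"`) and can be reused
#' on new data via the `stats` argument. A constant feature is set to 0 with
#' a warning.
#'
#' @param table Pixel table with at least 2 rows.
#' @param stats Optional list with `center` and `scale` vectors (as captured
#'   from a previous call) to apply instead of the table's own statistics.
#' @param sd_type `"population"` (divide by n) or `"sample"` (divide by
#'   n - 1).
#' @return The standardized table, with attribute `"standardization"`.
#' @export
standardize_features <- function(table, stats = NULL,
                                 sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  feats <- feature_columns(table)
  if (is.null(stats)) {
    if (nrow(table) < 2L) stop("need at least 2 rows", call. = FALSE)
    center <- vapply(feats, function(f) mean(table[[f]]), numeric(1))
    scale_ <- vapply(feats, function(f) {
      v <- table[[f]]
      s2 <- if (sd_type == "population") mean((v - mean(v))^2) else
        stats::var(v)
      sqrt(s2)
    }, numeric(1))
  } else {
    center <- stats$center[feats]
    scale_ <- stats$scale[feats]
  }
  for (f in feats) {
    if (scale_[[f]] > 0) {
      table[[f]] <- (table[[f]] - center[[f]]) / scale_[[f]]
    } else {
      warning(sprintf("feature '%s' is constant; standardized to 0", f),
              call. = FALSE)
      table[[f]] <- rep(0, nrow(table))
      scale_[[f]] <- 1
    }
  }
  attr(table, "standardization") <- list(center = center, scale = scale_,
                                         sd_type = sd_type)
  table
}

#' Stratified development/test split
#'
#' Splits the table into disjoint, exhaustive development and test parts.
#' The development size is `round(dev_fraction * n)` (half away from zero),
#' allocated across the two label strata by largest remainder so both
#' classes appear on both sides whenever possible.
#'
#' @param table Pixel table with a binary `label` column.
#' @param dev_fraction Development fraction in `(0, 1)` (default 0.8).
#' @param seed Integer seed.
#' @return List with elements `development` and `test`.
#' @export
split_dev_test <- function(table, dev_fraction = 0.8, seed = NULL) {
  if (dev_fraction <= 0 || dev_fraction >= 1) {
    stop("'dev_fraction' must be in (0, 1)", call. = FALSE)
  }
  n <- nrow(table)
  target <- round_half_up(dev_fraction * n)
  if (target < 1L || target >= n) stop("a split side would be empty",
                                       call. = FALSE)
  strata <- split(seq_len(n), table$label)
  exact <- vapply(strata, length, integer(1)) * dev_fraction
  base <- floor(exact)
  rem <- exact - base
  deficit <- target - sum(base)
  if (deficit > 0) {
    bump <- order(rem, decreasing = TRUE)[seq_len(deficit)]
    base[bump] <- base[bump] + 1L
  }
  # keep both classes on both sides where the stratum size allows it
  sizes <- vapply(strata, length, integer(1))
  base <- pmin(pmax(base, ifelse(sizes >= 2L, 1L, 0L)),
               ifelse(sizes >= 2L, sizes - 1L, sizes))
  dev_idx <- with_seed(seed, {
    unlist(Map(function(idx, k) {
      if (k <= 0L) integer(0) else sample(idx, k)
    }, strata, as.integer(base)), use.names = FALSE)
  })
  dev_idx <- sort(dev_idx)
  if (length(dev_idx) == 0L || length(dev_idx) == n) {
    stop("a split side would be empty", call. = FALSE)
  }
  list(development = table[dev_idx, , drop = FALSE],
       test = table[-dev_idx, , drop = FALSE])
}

#' Read or write a pixel table as CSV
#'
#' CSV with header `x,y,<features...>,label`, UTF-8, `.` decimal separator.
#' `meta`, when given, is written next to the CSV as `<path>.json` (useful
#' for provenance: well id, feature set, seeds, normalization and
#' standardization statistics).
#'
#' @param table Pixel table.
#' @param path CSV file path.
#' @param meta Optional list serialized as a JSON sidecar.
#' @return `write_pixel_table()` returns `path` invisibly;
#'   `read_pixel_table()` returns the table.
#' @export
write_pixel_table <- function(table, path, meta = NULL) {
  utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(meta)) {
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_pixel_table
#' @export
read_pixel_table <- function(path) {
  utils::read.csv(path, fileEncoding = "UTF-8")
}

#' The canonical pixel-table preparation chain
#'
#' Serialization, `[1, 255]` range normalization, random sampling, z-score
#' standardization and the stratified development/test split, in the fixed
#' order used throughout the experiments.
#'
#' @param maps Named list of feature maps (see [serialize_pixels()]).
#' @param mask Binary label mask.
#' @param fraction Sampling fraction (default 0.002).
#' @param dev_fraction Development fraction (default 0.8).
#' @param seed Integer seed driving both the sampling and the split.
#' @return List with `development`, `test` (standardized tables), `sampled`
#'   (the standardized sample before splitting) and `standardization`.
#' @export
prepare_dataset <- function(maps, mask, fraction = 0.002,
                            dev_fraction = 0.8, seed = NULL) {
  tab <- serialize_pixels(maps, mask)
  tab <- normalize_range(tab)
  tab <- sample_pixels(tab, fraction = fraction, seed = seed)
  tab <- standardize_features(tab)
  sp <- split_dev_test(tab, dev_fraction = dev_fraction,
                       seed = if (is.null(seed)) NULL else seed + 1L)
  list(development = sp$development, test = sp$test, sampled = tab,
       standardization = attr(tab, "standardization"))
}
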