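#' Configuration of a colony-classification experiment
#'
#' Bundles everything a full experiment needs: which cell-line regimes to
#' simulate (or which image/mask files to read), how many wells per line,
#' which feature sets to evaluate, the preparation fractions, the tuning
#' objective, and one master seed from which every random operation derives
#' its own recorded sub-seed.
#'
#' @param lines Named character vector mapping line names to synthetic
#'   regimes (see [generate_cell_line_suite()]), e.g.
#'   `c(MCF7 = "compact", `U87-MG` = "evanescent")`; or a list of
#'   `list(image = path, mask = path-or-NULL)` entries for real images.
#' @param wells_per_line Number of wells per line (default 30).
#' @param feature_sets Feature sets to evaluate (default all six).
#' @param window,levels Texture/entropy window and gray-level bins.
#' @param fraction,dev_fraction Sampling and development fractions.
#' @param objective Tuning objective.
#' @param use_synthetic_mask Use the generator's exact mask as ground truth
#'   instead of the entropy/sFCM segmentation (default `FALSE`: the ground
#'   truth is produced the same way as for real images).
#' @param min_area,opening_radius Mask post-processing parameters.
#' @param side Synthetic image side.
#' @param side_cap Encoding side cap.
#' @param seed Master seed.
#' @return List of class `"experiment_config"`.
#' @export
experiment_config <- function(lines = c(MCF7 = "compact",
                                        U251 = "large_merging",
                                        `MDA-MD-231` = "small_sparse",
                                        `U87-MG` = "evanescent"),
                              wells_per_line = 30L,
                              feature_sets = c("rgb", "luv", "contrast",
                                               "correlation", "energy",
                                               "homogeneity"),
                              window = 5L, levels = 256L,
                              fraction = 0.002, dev_fraction = 0.8,
                              objective = c("balanced_accuracy", "auroc"),
                              use_synthetic_mask = FALSE,
                              min_area = 50L, opening_radius = 1L,
                              side = 301L, side_cap = 4096L, seed = 1L) {
  objective <- match.arg(objective)
  feature_sets <- vapply(feature_sets, function(f)
    match.arg(f, c("rgb", "luv", "contrast", "correlation", "energy",
                   "homogeneity")), character(1), USE.NAMES = FALSE)
  structure(list(lines = lines, wells_per_line = as.integer(wells_per_line),
                 feature_sets = feature_sets, window = as.integer(window),
                 levels = as.integer(levels), fraction = fraction,
                 dev_fraction = dev_fraction, objective = objective,
                 use_synthetic_mask = isTRUE(use_synthetic_mask),
                 min_area = as.integer(min_area),
                 opening_radius = as.integer(opening_radius),
                 side = as.integer(side), side_cap = as.integer(side_cap),
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Enumerate the dataset runs of an experiment
#'
#' One run per line x well x feature set; the canonical study design
#' (4 lines x 30 wells x 6 feature sets) enumerates 720 runs.
#'
#' @param config An `"experiment_config"`.
#' @return Data frame with columns `line`, `well`, `feature_set`.
#' @export
enumerate_runs <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  line_names <- if (!is.null(names(config$lines)) &&
                    all(nzchar(names(config$lines)))) {
    names(config$lines)
  } else paste0("line", seq_along(config$lines))
  out <- expand.grid(feature_set = config$feature_sets,
                     well = seq_len(config$wells_per_line),
                     line = line_names,
                     stringsAsFactors = FALSE)
  out[, c("line", "well", "feature_set")]
}

#' Run a colony-classification experiment
#'
#' Executes the full pipeline for every enumerated run: synthetic well
#' generation (or image loading), feature-map extraction, ground-truth
#' segmentation (entropy + spatial fuzzy c-means + cleanup, unless the
#' generator's mask is requested), pixel-table preparation (serialize,
#' normalize to `[1, 255]`, random sample, standardize, stratified split),
#' cross-validated hyperparameter search for the Helstrom classifier, and
#' test-set scoring. Per-run failures are caught, logged in the manifest and
#' skipped.
#'
#' @param config An `"experiment_config"`.
#' @param progress Print one line per run to stderr.
#' @return List of class `"experiment_result"`: `config`, `runs` (per-run
#'   data frame with seeds, winning hyperparameters and test metrics),
#'   `summary` (mean and sd of each metric per line x feature set) and
#'   `skipped` (failed runs with reasons).
#' @export
run_experiment <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  runs <- enumerate_runs(config)
  line_names <- unique(runs$line)
  n_lines <- length(line_names)
  seeds <- with_seed(config$seed, list(
    line = stats::setNames(sample.int(.Machine$integer.max - 1L, n_lines),
                           line_names),
    run = sample.int(.Machine$integer.max - 1L, nrow(runs))))

  synthetic <- is.character(config$lines)
  rows <- vector("list", nrow(runs))
  skipped <- list()
  well_cache_line <- NULL
  wells <- NULL

  for (i in seq_len(nrow(runs))) {
    line <- runs$line[i]
    wi <- runs$well[i]
    fs <- runs$feature_set[i]
    if (!identical(well_cache_line, line)) {
      if (synthetic) {
        suite <- generate_cell_line_suite(config$lines[[line]],
                                          n_wells = config$wells_per_line,
                                          seed = seeds$line[[line]],
                                          side = config$side)
      } else {
        suite <- lapply(config$lines[[line]], function(e) {
          w <- read_well(e$image, e$mask)
          list(image = w$image, mask = w$mask, spec = NULL)
        })
      }
      # features and ground truth are shared across the six feature sets
      wells <- lapply(suite, function(w) {
        stack <- feature_stack(w$image, window = config$window,
                               levels = config$levels)
        truth <- if (config$use_synthetic_mask && !is.null(w$mask)) {
          w$mask
        } else {
          seg <- sfcm(stack$entropy)
          postprocess_mask(seg$mask, min_area = config$min_area,
                           opening_radius = config$opening_radius)
        }
        list(stack = stack, truth = truth)
      })
      well_cache_line <- line
    }
    res <- tryCatch({
      w <- wells[[wi]]
      maps <- w$stack[feature_set_maps(fs)]
      prep <- prepare_dataset(maps, w$truth, fraction = config$fraction,
                              dev_fraction = config$dev_fraction,
                              seed = seeds$run[i])
      gs <- suppressWarnings(
        grid_search(prep$development, objective = config$objective,
                    seed = seeds$run[i], side_cap = config$side_cap))
      m <- evaluate_model(gs, prep$test)
      data.frame(line = line, well = wi, feature_set = fs,
                 seed = seeds$run[i],
                 rescale = gs$best$rescale, encoding = gs$best$encoding,
                 copies = gs$best$copies, weighting = gs$best$weighting,
                 cv_score = max(gs$results$mean_score),
                 balanced_accuracy = m[["balanced_accuracy"]],
                 auroc = m[["auroc"]], jaccard = m[["jaccard"]],
                 dice = m[["dice"]])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- c(skipped, list(list(line = line, well = wi,
                                      feature_set = fs,
                                      reason = conditionMessage(res))))
      if (progress) message(sprintf("[%d/%d] %s well %d %s: SKIPPED (%s)",
                                    i, nrow(runs), line, wi, fs,
                                    conditionMessage(res)))
    } else {
      rows[[i]] <- res
      if (progress) message(sprintf("[%d/%d] %s well %d %s: BA %.3f",
                                    i, nrow(runs), line, wi, fs,
                                    res$balanced_accuracy))
    }
  }
  runs_df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  summary_df <- NULL
  if (!is.null(runs_df) && nrow(runs_df) > 0L) {
    agg <- function(fun, nm) {
      a <- stats::aggregate(
        runs_df[, c("balanced_accuracy", "auroc", "jaccard", "dice")],
        by = list(line = runs_df$line, feature_set = runs_df$feature_set),
        FUN = fun)
      names(a)[-(1:2)] <- paste0(names(a)[-(1:2)], nm)
      a
    }
    summary_df <- merge(agg(function(v) mean(v, na.rm = TRUE), "_mean"),
                        agg(function(v) stats::sd(v, na.rm = TRUE), "_sd"),
                        by = c("line", "feature_set"))
  }
  structure(list(config = config, seeds = seeds, runs = runs_df,
                 summary = summary_df, skipped = skipped),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  total <- nrow(enumerate_runs(x$config))
  done <- if (is.null(x$runs)) 0L else nrow(x$runs)
  cat(sprintf("Colony-classification experiment: %d of %d runs completed (%d skipped)\n",
              done, total, length(x$skipped)))
  if (!is.null(x$summary)) {
    cat("Mean test balanced accuracy by line and feature set:\n")
    print(x$summary[, c("line", "feature_set", "balanced_accuracy_mean",
                        "balanced_accuracy_sd")], digits = 3)
  }
  invisible(x)
}

#' Write an experiment manifest and score tables
#'
#' Writes `runs.csv` (per-run scores), `summary.csv` (per line x feature-set
#' aggregates) and `manifest.json` (config, seeds, skip reasons) into `dir`,
#' so every number in the tables is recomputable from the manifest alone.
#'
#' @param result An `"experiment_result"`.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_experiment <- function(result, dir) {
  stopifnot(inherits(result, "experiment_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p_runs <- file.path(dir, "runs.csv")
  p_sum <- file.path(dir, "summary.csv")
  p_man <- file.path(dir, "manifest.json")
  if (!is.null(result$runs)) {
    utils::write.csv(result$runs, p_runs, row.names = FALSE)
  }
  if (!is.null(result$summary)) {
    utils::write.csv(result$summary, p_sum, row.names = FALSE)
  }
  jsonlite::write_json(list(config = unclass(result$config),
                            seeds = result$seeds,
                            skipped = result$skipped),
                       p_man, auto_unbox = TRUE, digits = NA)
  invisible(c(runs = p_runs, summary = p_sum, manifest = p_man))
}
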