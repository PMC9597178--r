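# End-to-end orchestration: images + tree + trait table -> colour metrics
# -> transforms -> PGLS tables -> colour tree, with a resolved-config run
# log for provenance.

#' Pipeline run configuration
#'
#' Collects every tunable the pipeline uses, so a run can be replayed from
#' its logged config alone.
#'
#' @param image_dir Directory of masked RGBA PNGs named `<species>.png`
#'   (optional if `metrics` are supplied to [run_analysis()]).
#' @param tree_file Newick tree path.
#' @param traits_file CSV with columns `species`, `drum_speed`,
#'   `drum_length`, `body_mass`, `habitat`.
#' @param out_dir Output directory for report files (`NULL` = don't write).
#' @param cutoff Segmentation ΔE merge cutoff (default 45; 55 matches the
#'   looser published-figure setting).
#' @param bins_per_channel sRGB histogram bins per channel.
#' @param red_thresholds Named Lab thresholds for the red-patch criterion.
#' @param log_offset Offset for log10 of zero-containing columns.
#' @param lambda `"ml"` or a fixed value in `[0, 1]`.
#' @param habitat_covariate Include the habitat dummy in every model.
#' @param reversed Also fit the reversed-direction models (colour metric as
#'   response, drum traits + habitat as predictors).
#' @param seed Integer seed recorded with the run.
#' @return An object of class `run_config`.
#' @export
run_config <- function(image_dir = NULL, tree_file = NULL, traits_file = NULL,
                       out_dir = NULL, cutoff = 45, bins_per_channel = 3,
                       red_thresholds = c(L = 55, a = 30, b = 5),
                       log_offset = 0.01, lambda = "ml",
                       habitat_covariate = TRUE, reversed = TRUE,
                       seed = 1L) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (any(red_thresholds <= 0 & names(red_thresholds) == "L"))
    stop("red L threshold must be positive")
  if (is.numeric(lambda) && (lambda < 0 || lambda > 1))
    stop("fixed lambda must lie in [0, 1]")
  structure(as.list(environment()), class = "run_config")
}

#' Compute colour metrics for a directory of masked PNGs
#'
#' Loads every `*.png`, downsamples all images to the smallest image's
#' pixel width (common sampling frequency), segments them and computes the
#' four pattern metrics.
#'
#' @param image_dir Directory of RGBA PNGs; file names (minus extension)
#'   are the species names.
#' @param cfg A [run_config()].
#' @return List with `metrics` (data frame, one row per species) and
#'   `maps` (named list of `color_map`s at the common width).
#' @export
cohort_metrics <- function(image_dir, cfg = run_config()) {
  files <- sort(list.files(image_dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop("no PNG images found in ", image_dir)
  imgs <- lapply(files, load_masked_image)
  names(imgs) <- sub("\\.png$", "", basename(files))
  wmin <- min(vapply(imgs, image_width, numeric(1)))
  imgs <- lapply(imgs, resample_to_common_width, target_width = wmin)
  maps <- lapply(imgs, make_color_map, cutoff = cfg$cutoff,
                 bins_per_channel = cfg$bins_per_channel)
  met <- t(mapply(function(im, cm)
    pattern_metrics(im, cm = cm, red_thresholds = cfg$red_thresholds),
    imgs, maps))
  list(
    metrics = data.frame(species = names(imgs), met, row.names = NULL),
    maps = maps,
    common_width = wmin
  )
}

#' Run the full comparative analysis
#'
#' Merges per-species colour metrics (computed from `cfg$image_dir` or
#' supplied directly) with the trait table, log10-transforms the modelled
#' variables, residualizes drum speed on body mass, and fits the PGLS
#' models for both responses (mass-corrected drum speed and drum length)
#' with colour metrics and habitat as predictors — plus, optionally, the
#' reversed-direction fits. Also reports the predictor collinearity screen
#' and the neighbour-joining colour tree when image maps are available.
#'
#' @param cfg A [run_config()].
#' @param traits Optional trait data frame (instead of `cfg$traits_file`).
#' @param metrics Optional metrics data frame (instead of segmenting
#'   `cfg$image_dir`); columns `species` + the four metric columns.
#' @param tree Optional `phylo` tree (instead of `cfg$tree_file`).
#' @return An object of class `plumadrum_report`: list with `fits`
#'   (named list of `pgls_fit`), `reversed_fits`, `collinearity`,
#'   `metrics`, `transformed`, `color_tree` (or `NULL`), `config`.
#' @export
run_analysis <- function(cfg = run_config(), traits = NULL, metrics = NULL,
                         tree = NULL) {
  if (is.null(tree)) tree <- read_newick(cfg$tree_file)
  if (is.null(traits)) {
    traits <- utils::read.csv(cfg$traits_file, stringsAsFactors = FALSE)
  }
  need <- c("species", "drum_speed", "drum_length", "body_mass", "habitat")
  if (!all(need %in% names(traits)))
    stop("trait table must have columns: ", paste(need, collapse = ", "))
  maps <- NULL
  if (is.null(metrics)) {
    if (!is.null(cfg$image_dir)) {
      cm <- cohort_metrics(cfg$image_dir, cfg)
      metrics <- cm$metrics
      maps <- cm$maps
    } else {
      mcols <- c("chromatic_contrast", "achromatic_contrast",
                 "simpson_scaled", "red_proportion")
      if (!all(mcols %in% names(traits)))
        stop("no image_dir and trait table lacks the colour metric columns")
      metrics <- traits[, c("species", mcols)]
    }
  }
  tab <- merge(traits[, need], metrics, by = "species", sort = TRUE)
  if (nrow(tab) < 4) stop("fewer than 4 species after matching traits and ",
                          "metrics; check species names")
  mcols <- c("simpson_scaled", "chromatic_contrast", "achromatic_contrast",
             "red_proportion")
  tr <- transform_variables(
    tab, columns = c("drum_speed", "drum_length", "body_mass", mcols),
    offset = cfg$log_offset)
  tr$speed_resid <- mass_correct(tr$drum_speed, tr$body_mass)
  C <- phylo_covariance(tree, tr$species)

  if (cfg$habitat_covariate && length(unique(tr$habitat)) < 2)
    stop("habitat has a single level in the matched cohort; supply both ",
         "'closed' and 'open' species or set habitat_covariate = FALSE")
  pred_terms <- c("(intercept)", "colour diversity", "chromatic contrast",
                  "achromatic contrast", "red patch size")
  X <- cbind(1, tr$simpson_scaled, tr$chromatic_contrast,
             tr$achromatic_contrast, tr$red_proportion)
  if (cfg$habitat_covariate) {
    X <- cbind(X, tr$habitat)
    pred_terms <- c(pred_terms, "habitat")
  }
  colnames(X) <- pred_terms
  fits <- list(
    drum_speed = pgls_ml(X, tr$speed_resid, C, lambda = cfg$lambda),
    drum_length = pgls_ml(X, tr$drum_length, C, lambda = cfg$lambda)
  )

  reversed_fits <- NULL
  if (isTRUE(cfg$reversed)) {
    rterms <- c("(intercept)", "drum speed (resid)", "drum length")
    Xr <- cbind(1, tr$speed_resid, tr$drum_length)
    if (cfg$habitat_covariate) {
      Xr <- cbind(Xr, tr$habitat)
      rterms <- c(rterms, "habitat")
    }
    colnames(Xr) <- rterms
    reversed_fits <- lapply(stats::setNames(mcols, mcols), function(mc)
      pgls_ml(Xr, tr[[mc]], C, lambda = cfg$lambda))
  }

  screen <- collinearity_screen(tr[, mcols])
  ctree <- if (!is.null(maps) && length(maps) >= 3)
    neighbour_joining(color_distance_matrix(maps)) else NULL

  report <- structure(list(
    fits = fits, reversed_fits = reversed_fits, collinearity = screen,
    metrics = metrics, transformed = tr, color_tree = ctree, config = cfg
  ), class = "plumadrum_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' Write a report bundle to disk
#'
#' One CSV per fitted model (coefficient table preceded by `# Lambda/F/
#' d.f./model p` header lines), the metrics CSV, the collinearity matrix,
#' the colour tree as Newick (when present) and the resolved config as
#' JSON.
#'
#' @param report A `plumadrum_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_fit <- function(fit, path) {
    hdr <- sprintf(
      "# Lambda: %.6g\n# F-statistic: %.6g, %d and %d d.f.\n# model p-value: %.6g",
      fit$lambda, fit$F, fit$df[1], fit$df[2], fit$model_p)
    con <- file(path, "w")
    writeLines(hdr, con)
    utils::write.csv(fit$coefficients, con, row.names = FALSE)
    close(con)
  }
  for (nm in names(report$fits))
    write_fit(report$fits[[nm]], file.path(out_dir, paste0("pgls_", nm, ".csv")))
  for (nm in names(report$reversed_fits))
    write_fit(report$reversed_fits[[nm]],
              file.path(out_dir, paste0("pgls_reversed_", nm, ".csv")))
  utils::write.csv(report$metrics, file.path(out_dir, "color_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(report$collinearity$correlations,
                   file.path(out_dir, "collinearity.csv"))
  if (!is.null(report$color_tree))
    ape::write.tree(report$color_tree, file.path(out_dir, "color_tree.nwk"))
  cfg <- report$config
  cfg$lambda <- as.character(cfg$lambda)
  jsonlite::write_json(cfg[!vapply(cfg, is.null, TRUE)],
                       file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.plumadrum_report <- function(x, ...) {
  for (nm in names(x$fits)) {
    cat("==", nm, "~ colour metrics", if (x$config$habitat_covariate)
      "+ habitat", "==\n")
    print(x$fits[[nm]])
    cat("\n")
  }
  if (!x$collinearity$ok) {
    cat("Collinearity flags (|r| >= 0.7):\n")
    print(x$collinearity$flagged, row.names = FALSE)
  } else cat("Collinearity screen: all |r| < 0.7\n")
  invisible(x)
}

#' Sampling-frequency robustness check
#'
#' Recomputes the four colour metrics for every image at the reference
#' (common) width and at each alternative width fraction, then regresses
#' the alternative-scheme values on the reference values, one regression
#' per metric and scheme. A robust pipeline shows slope ~1 and r^2 near 1.
#'
#' @param specs List of [plumage_spec()] objects (or a directory path of
#'   PNGs, resolved like [cohort_metrics()]).
#' @param width_fractions Alternative widths as fractions of the reference
#'   width.
#' @param cfg A [run_config()].
#' @return Data frame with columns `metric`, `width_fraction`, `slope`,
#'   `r_squared`.
#' @export
sampling_robustness_check <- function(specs, width_fractions = c(0.75, 0.5),
                                      cfg = run_config()) {
  if (length(width_fractions) < 1) stop("need at least one width fraction")
  imgs <- if (is.character(specs)) {
    files <- sort(list.files(specs, pattern = "\\.png$", full.names = TRUE))
    lapply(files, load_masked_image)
  } else {
    lapply(specs, function(s) make_plumage_image(s)$image)
  }
  if (length(imgs) < 3) stop("need at least 3 images")
  wref <- min(vapply(imgs, image_width, numeric(1)))
  metrics_at <- function(w) {
    t(vapply(imgs, function(im)
      pattern_metrics(resample_to_common_width(im, w),
                      cutoff = cfg$cutoff,
                      bins_per_channel = cfg$bins_per_channel,
                      red_thresholds = cfg$red_thresholds),
      numeric(4)))
  }
  ref <- metrics_at(wref)
  out <- do.call(rbind, lapply(width_fractions, function(f) {
    alt <- metrics_at(max(2, round(f * wref)))
    do.call(rbind, lapply(colnames(ref), function(mc) {
      fit <- stats::lm(alt[, mc] ~ ref[, mc])
      data.frame(metric = mc, width_fraction = f,
                 slope = unname(stats::coef(fit)[2]),
                 r_squared = summary(fit)$r.squared)
    }))
  }))
  rownames(out) <- NULL
  out
}
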