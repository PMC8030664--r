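# Run configuration and the file-based pipeline -----------------------------

.config_defaults <- function() {
  list(
    paths = list(masks = NULL, behavior = NULL, atlas = NULL,
                 output = "svrlsm-out"),
    behavior = list(correction = "half_trial", threshold = 0.75,
                    dependent = "both"),
    lesions = list(min_subjects = 5L),
    grid = list(cost_min = 1e-2, cost_max = 1e9,
                gamma_min = 1e-9, gamma_max = 1e3),
    permutations = list(n = 1000L),
    alpha = 0.05,
    epsilon = 0.1,
    seed = 1L
  )
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a nested list, checks it against the
#' configuration schema (unknown keys and out-of-range values are
#' collected and reported together), and fills defaults. The decade grid
#' is built from `grid$cost_min/max` and `grid$gamma_min/max`.
#'
#' @param raw Path to a YAML document, or a (possibly partial) nested
#'   list; an empty input yields the full default configuration.
#' @return An object of class `run_config`.
#' @export
validate_config <- function(raw = list()) {
  if (is.character(raw) && length(raw) == 1L) raw <- yaml::read_yaml(raw)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("validate_config: configuration must be a list")
  def <- .config_defaults()
  problems <- character()
  bad_top <- setdiff(names(raw), names(def))
  if (length(bad_top))
    problems <- c(problems, paste0("unknown key(s): ",
                                   paste(bad_top, collapse = ", ")))
  cfg <- def
  for (nm in intersect(names(raw), names(def))) {
    if (is.list(def[[nm]])) {
      sub <- raw[[nm]]
      bad <- setdiff(names(sub), names(def[[nm]]))
      if (length(bad))
        problems <- c(problems, paste0("unknown key(s) under '", nm, "': ",
                                       paste(bad, collapse = ", ")))
      for (k in intersect(names(sub), names(def[[nm]])))
        cfg[[nm]][[k]] <- sub[[k]]
    } else {
      cfg[[nm]] <- raw[[nm]]
    }
  }
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  chk(is.numeric(cfg$alpha) && cfg$alpha > 0 && cfg$alpha < 1,
      "alpha must lie in (0, 1)")
  chk(is.numeric(cfg$epsilon) && cfg$epsilon >= 0, "epsilon must be >= 0")
  chk(is.numeric(cfg$seed) && cfg$seed == round(cfg$seed),
      "seed must be an integer")
  chk(cfg$permutations$n >= 1, "permutations$n must be >= 1")
  chk(cfg$lesions$min_subjects >= 1, "lesions$min_subjects must be >= 1")
  chk(cfg$behavior$threshold > 0.5 && cfg$behavior$threshold < 1,
      "behavior$threshold must lie in (0.5, 1)")
  chk(cfg$behavior$correction %in% c("half_trial", "none"),
      "behavior$correction must be 'half_trial' or 'none'")
  chk(cfg$behavior$dependent %in%
        c("both", "span_phonological", "span_semantic"),
      "behavior$dependent must be 'both', 'span_phonological' or 'span_semantic'")
  g <- cfg$grid
  chk(g$cost_min >= 1e-2 && g$cost_max <= 1e9 && g$cost_min <= g$cost_max,
      "grid cost range must lie within [0.01, 1e9]")
  chk(g$gamma_min >= 1e-9 && g$gamma_max <= 1e3 &&
        g$gamma_min <= g$gamma_max,
      "grid gamma range must lie within [1e-9, 1e3]")
  if (length(problems))
    stop("validate_config: invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  cfg$seed <- as.integer(cfg$seed)
  cfg$permutations$n <- as.integer(cfg$permutations$n)
  cfg$lesions$min_subjects <- as.integer(cfg$lesions$min_subjects)
  structure(cfg, class = "run_config")
}

# decade grid spanning the configured ranges
.config_grid <- function(cfg) {
  default_grid(cost = 10^seq(log10(cfg$grid$cost_min),
                             log10(cfg$grid$cost_max)),
               gamma = 10^seq(log10(cfg$grid$gamma_min),
                              log10(cfg$grid$gamma_max)))
}

#' Run the full lesion-symptom pipeline from a configuration
#'
#' Loads the lesion masks and behavioral trial table named in the
#' configuration, scores the behavior, assembles the nuisance covariates
#' for each working-memory measure (lesion size in voxels, the
#' input-processing principal-component composite, and the opposing
#' measure), and fits [svrlsm] for the requested dependent variable(s).
#' Results (NIfTI beta/p/significance maps, grid-search JSON, region and
#' score TSVs, a text report) are written under the configured output
#' directory.
#'
#' @param config A [validate_config] result, a raw list, or a YAML path.
#' @return Invisibly, a named list of `svrlsm` fits (one per dependent).
#' @export
run_lsm <- function(config) {
  cfg <- if (inherits(config, "run_config")) config
         else validate_config(config)
  if (is.null(cfg$paths$masks) || is.null(cfg$paths$behavior))
    stop("run_lsm: paths$masks and paths$behavior are required")
  mask_paths <- cfg$paths$masks
  if (length(mask_paths) == 1L && dir.exists(mask_paths))
    mask_paths <- sort(list.files(mask_paths, pattern = "\\.nii(\\.gz)?$",
                                  full.names = TRUE))
  masks <- load_cohort(mask_paths)
  trials <- read_behavior(cfg$paths$behavior)
  scores <- score_behavior(trials, threshold = cfg$behavior$threshold,
                           correction = cfg$behavior$correction)
  ids <- vapply(masks, function(m) m$subject_id, character(1))
  scores <- scores[match(ids, scores$subject_id), , drop = FALSE]
  if (anyNA(scores$subject_id))
    stop("run_lsm: behavioral scores missing for some mask subjects")
  lm <- build_matrix(masks, min_subjects = cfg$lesions$min_subjects)
  voxvol <- prod(lm$voxel_dims)
  lesion_size_vox <- lm$lesion_volumes_mm3 / voxvol
  comp <- compute_composite(scores$dprime_phonological,
                            scores$dprime_semantic)
  atlas <- if (!is.null(cfg$paths$atlas)) {
    img <- RNifti::readNifti(cfg$paths$atlas)
    array(as.integer(img), dim(img))
  }
  deps <- if (cfg$behavior$dependent == "both")
    c("span_phonological", "span_semantic") else cfg$behavior$dependent
  out_dir <- cfg$paths$output
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_scores(cbind(scores, input_composite = comp$scores),
               file.path(out_dir, "scores.tsv"),
               meta = list(correction = cfg$behavior$correction,
                           threshold = cfg$behavior$threshold,
                           composite_loadings = as.list(comp$loadings),
                           composite_explained_variance =
                             comp$explained_variance))
  fits <- list()
  for (dep in deps) {
    other <- setdiff(c("span_phonological", "span_semantic"), dep)
    covs <- list(lesion_size = lesion_size_vox,
                 input_processing = comp$scores)
    covs[[other]] <- scores[[other]]
    fit <- svrlsm(scores[[dep]], lm, covariates = covs,
                  grid = .config_grid(cfg), n_perm = cfg$permutations$n,
                  alpha = cfg$alpha, epsilon = cfg$epsilon,
                  seed = cfg$seed, atlas = atlas)
    dd <- file.path(out_dir, dep)
    write_results(fit, dd)
    fits[[dep]] <- fit
  }
  invisible(fits)
}

#' Write the maps, tables and report of a fitted model
#'
#' @param fit An `svrlsm` fit.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_results <- function(fit, dir) {
  stopifnot(inherits(fit, "svrlsm"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  aff <- fit$patches$affine
  write_map(ifelse(is.na(fit$maps$beta), 0, fit$maps$beta),
            file.path(dir, "beta.nii.gz"), affine = aff)
  write_map(ifelse(is.na(fit$maps$p), 1, fit$maps$p),
            file.path(dir, "p.nii.gz"), affine = aff)
  write_map(fit$maps$significant, file.path(dir, "significant.nii.gz"),
            affine = aff)
  jsonlite::write_json(
    list(grid = fit$grid_search$grid,
         chosen = fit$grid_search$chosen,
         model_p = fit$grid_search$model_p,
         n_perm = fit$grid_search$n_perm,
         seed = fit$seed,
         alpha = fit$alpha,
         n_significant_patches = sum(fit$inference$significant),
         n_resampled = fit$inference$n_resampled),
    file.path(dir, "grid_search.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(fit$regions))
    write.table(fit$regions, file.path(dir, "regions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  writeLines(write_report(fit), file.path(dir, "report.txt"))
  invisible(dir)
}

#' Human-readable run report
#'
#' Deterministic text summary of a fitted model: data dimensions, chosen
#' hyperparameters, model significance, seed, and the region table (sorted
#' by volume, descending). Can equally be regenerated from the saved
#' grid-search JSON plus region TSV of a previous run.
#'
#' @param fit An `svrlsm` fit, or `NULL` for a header-only report.
#' @return Character vector of report lines.
#' @export
write_report <- function(fit = NULL) {
  lines <- c("Multivariate SVR lesion-symptom mapping report",
             "==============================================")
  if (is.null(fit)) return(lines)
  gs <- fit$grid_search
  pm <- fit$patches
  nsig <- sum(fit$inference$significant)
  vsig <- sum(pm$patch_sizes[fit$inference$significant])
  lines <- c(lines,
    sprintf("subjects: %d", nrow(pm$matrix)),
    sprintf("covered voxels: %d in %d patches", length(pm$voxel_index),
            ncol(pm$matrix)),
    sprintf("covariates: %s",
            if (length(fit$dependent$covariates_used))
              paste(fit$dependent$covariates_used, collapse = ", ")
            else "(none)"),
    sprintf("chosen hyperparameters: cost = %g, gamma = %g, epsilon = %g",
            gs$chosen$cost, gs$chosen$gamma, gs$chosen$epsilon),
    sprintf("model p (permutation rank of CV MSE): %.4g", gs$model_p),
    sprintf("permutations: %d, seed: %d, alpha: %g", fit$n_perm,
            as.integer(fit$seed), fit$alpha),
    sprintf("significant negative-beta patches: %d (%d voxels, %.0f mm^3)",
            nsig, vsig, vsig * prod(pm$voxel_dims)))
  if (fit$inference$n_resampled > 0)
    lines <- c(lines, sprintf("failed permutations resampled: %d",
                              fit$inference$n_resampled))
  if (!is.null(fit$regions) && nrow(fit$regions)) {
    lines <- c(lines, "", "significant damage by region (mm^3, descending):")
    r <- fit$regions
    lines <- c(lines, sprintf("  %s (label %d): %.0f mm^3%s",
                              r$region_name, r$region_label, r$volume_mm3,
                              ifelse(r$above_threshold, "",
                                     " [sub-threshold]")))
  }
  lines
}
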