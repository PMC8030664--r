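#' Fit a multivariate SVR lesion-symptom model
#'
#' The central fitting function. Starting from a behavioral score and a
#' cohort of binary lesion masks, it (1) residualizes the score against
#' the supplied nuisance covariates and min-max scales the residuals to
#' `[0, 1]`; (2) builds the subjects x voxels matrix, applies the
#' minimum-coverage filter and compresses identical columns into patches;
#' (3) selects the RBF-SVR hyperparameters by permutation-ranked
#' cross-validated error over a (cost, gamma) grid; (4) assigns per-patch
#' one-sided significance by permutation on the back-projected beta map;
#' and (5) expands the patch statistics to voxel maps (and, when an atlas
#' is supplied, a region table).
#'
#' @param y Numeric behavioral score, one per subject, or a
#'   `dependent_vector` from [residualize_and_scale] (then `covariates` is
#'   ignored).
#' @param lesions A list of [lesion_mask] objects, a `lesion_matrix`, or a
#'   `patched_matrix`.
#' @param covariates Named list/data.frame of nuisance covariates (e.g.
#'   lesion size, input-processing composite, the opposing score).
#' @param grid Candidate hyperparameters; see [default_grid()].
#' @param n_perm Permutations for both hyperparameter selection and patch
#'   inference; default 1000.
#' @param alpha Significance threshold for patches (and the model);
#'   default 0.05.
#' @param epsilon SVR tube half-width; default 0.1.
#' @param k Cross-validation folds; default 5.
#' @param min_subjects Coverage filter when `lesions` are masks; default 5.
#' @param seed Master seed; all randomness (folds, both permutation
#'   streams) derives from it through named substreams.
#' @param atlas Optional 3D integer label array on the cohort grid.
#' @param region_names Optional label -> name lookup for the region table.
#' @param reuse_selection_permutations Passed to [patch_inference].
#' @return An object of class `svrlsm` with print, summary, coef,
#'   predict, fitted, residuals and plot methods.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(sim_config(n_subjects = 30, seed = 7))
#' scores <- score_behavior(cohort$trials)
#' fit <- svrlsm(scores$span_phonological, cohort$masks,
#'               covariates = list(lesion_size = cohort$lesion_volumes),
#'               grid = default_grid(cost = c(1, 100), gamma = c(0.01, 1)),
#'               n_perm = 99, seed = 7)
#' print(fit)
#' }
#' @export
svrlsm <- function(y, lesions, covariates = NULL, grid = default_grid(),
                   n_perm = 1000L, alpha = 0.05, epsilon = 0.1, k = 5L,
                   min_subjects = 5L, seed = 1L, atlas = NULL,
                   region_names = NULL,
                   reuse_selection_permutations = FALSE) {
  # lesion design
  if (inherits(lesions, "patched_matrix")) {
    pm <- lesions
    lm <- NULL
  } else {
    lm <- if (inherits(lesions, "lesion_matrix")) lesions
          else build_matrix(lesions, min_subjects = min_subjects)
    pm <- compress_patches(lm)
  }
  n <- nrow(pm$matrix)
  # dependent variable
  dv <- if (inherits(y, "dependent_vector")) y
        else residualize_and_scale(y, covariates,
                                   subject_ids = pm$subject_ids)
  if (length(dv$scaled) != n)
    stop("svrlsm: y and lesion data disagree on the number of subjects")
  X <- pm$matrix
  m <- pm$patch_sizes
  gs <- select_params(X, dv$scaled, grid = grid, n_perm = n_perm, k = k,
                      epsilon = epsilon, seed = seed, multiplicities = m)
  inf <- patch_inference(X, dv$scaled, cost = gs$chosen$cost,
                         gamma = gs$chosen$gamma, epsilon = epsilon,
                         n_perm = n_perm, alpha = alpha, seed = seed,
                         multiplicities = m,
                         reuse_selection_permutations =
                           reuse_selection_permutations)
  maps <- list(beta = expand_map(inf$patch_beta, pm),
               p = expand_map(inf$patch_p, pm),
               significant = expand_map(as.numeric(inf$significant), pm,
                                        missing = 0))
  regions <- if (!is.null(atlas)) {
    summarize_regions(maps$significant, atlas, voxel_dims = pm$voxel_dims,
                      region_names = region_names)
  }
  structure(list(
    dependent = dv, patches = pm, lesion_matrix = lm,
    grid_search = gs, inference = inf, model = inf$model,
    maps = maps, regions = regions,
    alpha = alpha, n_perm = as.integer(n_perm), seed = seed
  ), class = "svrlsm")
}

#' @export
print.svrlsm <- function(x, ...) {
  pm <- x$patches
  cat("Multivariate SVR lesion-symptom model\n")
  cat(sprintf("  %d subjects, %d covered voxels in %d patches (grid %s)\n",
              nrow(pm$matrix), length(pm$voxel_index), ncol(pm$matrix),
              paste(pm$dim, collapse = "x")))
  cat(sprintf("  dependent: residualized on {%s}, scaled to [0, 1]\n",
              if (length(x$dependent$covariates_used))
                paste(x$dependent$covariates_used, collapse = ", ")
              else "intercept only"))
  cat(sprintf("  chosen hyperparameters: cost = %g, gamma = %g (model p = %.4g)\n",
              x$grid_search$chosen$cost, x$grid_search$chosen$gamma,
              x$grid_search$model_p))
  nsig <- sum(x$inference$significant)
  vsig <- sum(pm$patch_sizes[x$inference$significant])
  cat(sprintf("  significant patches at p < %g (beta < 0): %d (%d voxels, %.0f mm^3)\n",
              x$alpha, nsig, vsig, vsig * prod(pm$voxel_dims)))
  invisible(x)
}

#' @param object,x An `svrlsm` fit.
#' @param ... Unused.
#' @rdname svrlsm
#' @export
summary.svrlsm <- function(object, ...) {
  g <- object$grid_search$grid
  structure(list(fit = object,
                 top_grid = utils::head(g[order(g$perm_p, g$cv_mse), ], 5L),
                 regions = object$regions),
            class = "summary.svrlsm")
}

#' @export
print.summary.svrlsm <- function(x, ...) {
  print(x$fit)
  cat("\nBest hyperparameter pairs:\n")
  print(x$top_grid, row.names = FALSE, digits = 4)
  if (!is.null(x$regions) && nrow(x$regions)) {
    cat("\nSignificant damage by region (volume descending):\n")
    print(x$regions, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @param voxel If `TRUE`, return the beta map expanded to the voxel grid
#'   instead of per-patch values.
#' @rdname svrlsm
#' @export
coef.svrlsm <- function(object, voxel = FALSE, ...) {
  if (voxel) object$maps$beta else object$inference$patch_beta
}

#' @param newdata New lesion data: a list of [lesion_mask], or a matrix on
#'   the model's retained voxels (or patches).
#' @rdname svrlsm
#' @export
predict.svrlsm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(predict(object$model))
  pm <- object$patches
  if (is.list(newdata) && inherits(newdata[[1L]], "lesion_mask")) {
    newdata <- do.call(rbind, lapply(newdata, function(msk) {
      as.vector(msk$volume)[pm$voxel_index]
    }))
  }
  newdata <- as.matrix(newdata)
  if (ncol(newdata) == length(pm$voxel_index)) {
    # collapse voxel columns onto patches (any member column; they are
    # identical by construction for training data, representative otherwise)
    newdata <- newdata[, !duplicated(pm$patch_of_voxel), drop = FALSE]
  } else if (ncol(newdata) != ncol(pm$matrix)) {
    stop("predict.svrlsm: newdata must have one column per retained voxel or per patch")
  }
  predict(object$model, newdata)
}

#' @rdname svrlsm
#' @export
fitted.svrlsm <- function(object, ...) predict(object$model)

#' @rdname svrlsm
#' @export
residuals.svrlsm <- function(object, ...) {
  object$dependent$scaled - fitted(object)
}

#' @param slices Axial (third-dimension) slice indices to draw; default
#'   four slices spanning the covered extent.
#' @param what `"beta"`, `"p"` or `"significant"`.
#' @rdname svrlsm
#' @export
plot.svrlsm <- function(x, slices = NULL, what = c("beta", "p", "significant"),
                        ...) {
  what <- match.arg(what)
  arr <- x$maps[[what]]
  d <- dim(arr)
  if (is.null(slices)) {
    zz <- which(apply(!is.na(arr) & arr != 0, 3L, any))
    if (length(zz) == 0L) zz <- round(d[3L] / 2)
    slices <- unique(round(quantile(zz, c(0.2, 0.4, 0.6, 0.8))))
  }
  op <- graphics::par(mfrow = c(1, length(slices)), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  pal <- grDevices::hcl.colors(65, if (what == "beta") "Blue-Red 3" else "viridis")
  rng <- range(arr, na.rm = TRUE)
  if (what == "beta") rng <- c(-1, 1) * max(abs(rng))
  for (z in slices) {
    graphics::image(arr[, , z], zlim = rng, col = pal, axes = FALSE,
                    main = sprintf("%s, slice z = %d", what, z), ...)
  }
  invisible(x)
}
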