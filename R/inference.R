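# Hyperparameter selection and permutation inference ------------------------

#' Decade grid of SVR hyperparameters
#'
#' Cost and gamma in decade steps over the canonical search ranges
#' (cost 0.01 to 1e9, gamma 1e-9 to 1e3), 12 x 13 = 156 pairs by default.
#'
#' @param cost,gamma Numeric vectors of candidate values.
#' @return Data.frame with columns `cost` and `gamma`.
#' @export
default_grid <- function(cost = 10^seq(-2, 9), gamma = 10^seq(-9, 3)) {
  if (any(cost < 0.01 - 1e-12) || any(cost > 1e9 + 1))
    stop("default_grid: cost outside the search range [0.01, 1e9]")
  if (any(gamma < 1e-9 * (1 - 1e-9)) || any(gamma > 1e3 + 1e-6))
    stop("default_grid: gamma outside the search range [1e-9, 1e3]")
  expand.grid(cost = cost, gamma = gamma, KEEP.OUT.ATTRS = FALSE)
}

# Draw n_perm permutations of 1:n as an n_perm x n integer matrix.
.perm_matrix <- function(n, n_perm, seed) {
  .with_seed(seed, t(replicate(n_perm, sample.int(n))))
}

#' Select SVR hyperparameters by permutation-ranked cross-validated error
#'
#' For each candidate (cost, gamma) pair, computes the 5-fold
#' cross-validated MSE of the real model and of `n_perm` models fit to
#' permuted (shuffled) dependent scores, and ranks the real error in the
#' permutation null: `perm_p = (1 + #permuted MSE <= real MSE) /
#' (n_perm + 1)`. The pair with the lowest permutation p-value is chosen;
#' its p-value is reported as the model significance. Ties on the p-value
#' (common once many pairs saturate the permutation resolution) are broken
#' toward the most regularized model -- smallest cost, then smallest gamma
#' -- since among statistically indistinguishable pairs the smoothest fit
#' yields the most stable beta map for the downstream inference. The same
#' fold partition and the same permutation set are used for every pair, so
#' pairs are compared on identical resamples.
#'
#' @inheritParams cv_mse
#' @param grid Data.frame of candidate `cost`/`gamma` pairs, e.g. from
#'   [default_grid()].
#' @param n_perm Number of permutations; default 1000.
#' @return An object of class `svrlsm_grid`: the evaluated `grid` (with
#'   `cv_mse` and `perm_p` columns), the `chosen` parameters, `model_p`,
#'   `n_perm` and `seed`.
#' @export
select_params <- function(X, y, grid = default_grid(), n_perm = 1000L,
                          k = 5L, epsilon = 0.1, seed = 1L,
                          multiplicities = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (nrow(grid) == 0L) stop("select_params: empty grid")
  if (k > n) stop("select_params: more folds than subjects")
  Xm <- .scale_mult(X, multiplicities)
  D2 <- .row_dist2(Xm)
  fold_id <- .cv_folds(n, k, .sub_seed(seed, "cv_folds"))
  perms <- .perm_matrix(n, n_perm, .sub_seed(seed, "select_perms"))
  res <- lapply(seq_len(nrow(grid)), function(g) {
    K <- exp(-grid$gamma[g] * D2)
    real <- .cv_mse_kernel(K, y, fold_id, grid$cost[g], epsilon)
    null <- vapply(seq_len(n_perm), function(b) {
      .cv_mse_kernel(K, y[perms[b, ]], fold_id, grid$cost[g], epsilon)
    }, numeric(1))
    c(real, (1 + sum(null <= real)) / (n_perm + 1))
  })
  res <- do.call(rbind, res)
  out <- cbind(grid, cv_mse = res[, 1L], perm_p = res[, 2L])
  ord <- order(out$perm_p, out$cost, out$gamma)
  best <- out[ord[1L], ]
  structure(list(
    grid = out,
    chosen = list(cost = best$cost, gamma = best$gamma, epsilon = epsilon),
    model_p = best$perm_p,
    n_perm = as.integer(n_perm),
    k = as.integer(k),
    seed = seed
  ), class = "svrlsm_grid")
}

#' @export
print.svrlsm_grid <- function(x, ...) {
  cat(sprintf(paste0("Hyperparameter search over %d (cost, gamma) pairs, ",
                     "%d permutations\n"), nrow(x$grid), x$n_perm))
  cat(sprintf("  chosen: cost = %g, gamma = %g (model p = %.4g)\n",
              x$chosen$cost, x$chosen$gamma, x$model_p))
  invisible(x)
}

#' Per-patch permutation inference on the SVR beta map
#'
#' Fits the model at the chosen hyperparameters, back-projects the beta
#' map, then refits on `n_perm` shuffles of the dependent scores to build
#' each patch's permutation null. The one-sided (lower-tail) p-value is
#' `(1 + #permuted beta <= observed beta) / (n_perm + 1)`: damage is
#' expected to lower performance, so only negative betas are of interest,
#' and a patch is significant when `p < alpha` and its observed beta is
#' negative. P-values are reported per patch without correction across
#' patches; set `fdr = TRUE` to add Benjamini-Hochberg adjusted values.
#'
#' @inheritParams fit_svr
#' @param n_perm Number of permutations; default 1000.
#' @param alpha Significance threshold; default 0.05.
#' @param seed Master seed; permutations come from the inference
#'   substream (or the selection substream when
#'   `reuse_selection_permutations = TRUE`).
#' @param fdr Also report Benjamini-Hochberg adjusted p-values.
#' @param reuse_selection_permutations Reuse the permutation stream of
#'   [select_params] instead of a fresh one.
#' @return An object of class `lsm_inference`: `patch_beta`, `patch_p`,
#'   `significant`, the fitted `model`, `n_perm`, `alpha`, `seed`, and the
#'   count of resampled failed permutations.
#' @export
patch_inference <- function(X, y, cost, gamma, epsilon = 0.1,
                            n_perm = 1000L, alpha = 0.05, seed = 1L,
                            multiplicities = NULL, fdr = FALSE,
                            reuse_selection_permutations = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  fit <- fit_svr(X, y, cost = cost, gamma = gamma, epsilon = epsilon,
                 multiplicities = multiplicities)
  beta <- beta_map(fit)
  K <- exp(-gamma * .row_dist2(fit$Xm))
  stream <- if (reuse_selection_permutations) "select_perms"
            else "inference_perms"
  perms <- .perm_matrix(n, n_perm, .sub_seed(seed, stream))
  extra_seed <- .sub_seed(seed, stream) + 1L
  count_le <- numeric(ncol(X))
  n_failed <- 0L
  b <- 1L
  while (b <= n_perm) {
    perm_beta <- tryCatch({
      sol <- .smo_svr(K, y[perms[b, ]], cost, epsilon, 1e-3)
      if (all(sol$coefs == 0)) stop("no support vectors")
      drop(crossprod(X, sol$coefs))
    }, error = function(e) NULL)
    if (is.null(perm_beta)) {
      # failed permutation: resample it and log the failure
      n_failed <- n_failed + 1L
      if (n_failed > 10L * n_perm)
        stop("patch_inference: permutation fits keep failing")
      perms[b, ] <- .with_seed(extra_seed + n_failed, sample.int(n))
      next
    }
    count_le <- count_le + (perm_beta <= beta)
    b <- b + 1L
  }
  p <- (1 + count_le) / (n_perm + 1)
  out <- list(patch_beta = beta,
              patch_p = p,
              significant = (p < alpha) & (beta < 0),
              model = fit,
              n_perm = as.integer(n_perm),
              alpha = alpha,
              seed = seed,
              n_resampled = n_failed)
  if (fdr) out$patch_p_fdr <- stats::p.adjust(p, method = "BH")
  structure(out, class = "lsm_inference")
}

#' @export
print.lsm_inference <- function(x, ...) {
  cat(sprintf(paste0("Patch permutation inference: %d patches, %d ",
                     "permutations, alpha = %g\n"),
              length(x$patch_beta), x$n_perm, x$alpha))
  cat(sprintf("  significant (negative-beta) patches: %d",
              sum(x$significant)))
  if (x$n_resampled > 0)
    cat(sprintf("  [%d failed permutations resampled]", x$n_resampled))
  cat("\n")
  invisible(x)
}
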