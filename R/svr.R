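# Kernel helpers ------------------------------------------------------------

# Pairwise squared Euclidean distances between rows (optionally between two
# row sets). Multiplicity weights m_j enter as column scaling by sqrt(m_j),
# so the RBF kernel on the patch representation,
#   k(u, v) = exp(-gamma * sum_j m_j (u_j - v_j)^2),
# equals the plain RBF kernel on the expanded voxel matrix.
.row_dist2 <- function(A, B = NULL) {
  if (is.null(B)) {
    G <- tcrossprod(A)
    d <- diag(G)
    pmax(outer(d, d, "+") - 2 * G, 0)
  } else {
    pmax(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B), 0)
  }
}

.scale_mult <- function(X, multiplicities = NULL) {
  if (is.null(multiplicities)) return(X)
  if (length(multiplicities) != ncol(X))
    stop("multiplicities must have one entry per column of X")
  sweep(X, 2L, sqrt(multiplicities), "*")
}

# Evaluate an expression with a private, restored RNG state.
.with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Fitting --------------------------------------------------------------------

#' Fit an epsilon-insensitive RBF support vector regression
#'
#' Fits `y ~ X` with kernel
#' `k(u, v) = exp(-gamma * sum_j m_j (u_j - v_j)^2)`, where `m_j` is an
#' optional per-column multiplicity (for patch-compressed lesion matrices,
#' the patch's voxel count). With multiplicities supplied, the fit on the
#' compressed representation is exactly the fit on the expanded voxel
#' matrix. The dual problem is solved by the package's SMO solver on the
#' precomputed kernel matrix.
#'
#' @param X Numeric matrix, subjects x features (patches).
#' @param y Numeric response, typically residualized scores scaled to
#'   `[0, 1]`.
#' @param cost Regularization constant C (> 0).
#' @param gamma RBF width (> 0).
#' @param epsilon Insensitivity tube half-width; default 0.1.
#' @param multiplicities Optional per-column voxel counts.
#' @param tol SMO convergence tolerance; default 1e-3 (the libsvm default).
#' @return An object of class `svr_fit` with dual `coefs` (one per
#'   subject, zero off the support set), bias `b`, support indices `sv`,
#'   and the training inputs.
#' @export
fit_svr <- function(X, y, cost, gamma, epsilon = 0.1,
                    multiplicities = NULL, tol = 1e-3) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("fit_svr: need at least 2 subjects")
  if (length(y) != nrow(X)) stop("fit_svr: length(y) != nrow(X)")
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("fit_svr: non-finite inputs")
  if (sd(y) == 0) stop("fit_svr: y is constant; nothing to regress")
  if (cost <= 0 || gamma <= 0 || epsilon < 0)
    stop("fit_svr: require cost > 0, gamma > 0, epsilon >= 0")
  Xm <- .scale_mult(X, multiplicities)
  K <- exp(-gamma * .row_dist2(Xm))
  sol <- .smo_svr(K, y, cost, epsilon, tol)
  if (!sol$converged)
    warning("fit_svr: SMO did not converge within the iteration cap")
  structure(list(coefs = sol$coefs, b = sol$b,
                 sv = which(sol$coefs != 0),
                 cost = cost, gamma = gamma, epsilon = epsilon,
                 X = X, Xm = Xm, multiplicities = multiplicities,
                 converged = sol$converged, iterations = sol$iterations),
            class = "svr_fit")
}

#' @export
print.svr_fit <- function(x, ...) {
  cat(sprintf(paste0("RBF-kernel eps-SVR: n = %d, features = %d, ",
                     "C = %g, gamma = %g, epsilon = %g, %d support vectors\n"),
              nrow(x$X), ncol(x$X), x$cost, x$gamma, x$epsilon,
              length(x$sv)))
  invisible(x)
}

#' @param object An `svr_fit`.
#' @param newdata Matrix of new rows on the same features (defaults to the
#'   training matrix).
#' @param ... Unused.
#' @rdname fit_svr
#' @export
predict.svr_fit <- function(object, newdata = NULL, ...) {
  Xm_new <- if (is.null(newdata)) object$Xm
            else .scale_mult(as.matrix(newdata), object$multiplicities)
  K <- exp(-object$gamma * .row_dist2(Xm_new, object$Xm))
  drop(K %*% object$coefs) + object$b
}

#' Back-projected beta map of a fitted SVR
#'
#' The per-feature sensitivity map `beta_j = sum_i alpha_i X_ij` over the
#' support vectors (dual-coefficient back-projection), the standard
#' multivariate SVR lesion-symptom map; its ranking is what permutation
#' inference consumes. The alternative `"gradient"` method returns the
#' training-sample average of the analytic kernel gradient
#' `dF/dx_j`, a finite-width sensitivity map.
#'
#' @param fit An `svr_fit`.
#' @param method `"backprojection"` (default) or `"gradient"`.
#' @return Numeric vector, one beta per feature (patch).
#' @export
beta_map <- function(fit, method = c("backprojection", "gradient")) {
  stopifnot(inherits(fit, "svr_fit"))
  method <- match.arg(method)
  if (length(fit$sv) == 0L)
    stop("beta_map: model has no support vectors")
  if (method == "backprojection")
    return(drop(crossprod(fit$X, fit$coefs)))
  # average gradient: dF/dx_j (x) = sum_i c_i K(x, x_i) * (-2 gamma m_j (x_j - x_ij))
  m <- fit$multiplicities %||% rep(1, ncol(fit$X))
  K <- exp(-fit$gamma * .row_dist2(fit$Xm))
  Wc <- K * rep(fit$coefs, each = nrow(K))       # Wc[r, i] = c_i K(x_r, x_i)
  G <- -2 * fit$gamma *
    (fit$X * rowSums(Wc) - Wc %*% fit$X)         # rows: gradient at x_r
  colMeans(G) * m
}

# Cross-validation -----------------------------------------------------------

# Fold assignment: seeded shuffled split into k groups of near-equal size.
.cv_folds <- function(n, k, seed) {
  .with_seed(seed, sample(rep_len(seq_len(k), n)))
}

# Mean over folds of held-out MSE, on a precomputed kernel matrix.
.cv_mse_kernel <- function(K, y, fold_id, cost, epsilon, tol = 1e-3) {
  folds <- sort(unique(fold_id))
  mse <- vapply(folds, function(f) {
    tr <- which(fold_id != f)
    te <- which(fold_id == f)
    sol <- .smo_svr(K[tr, tr, drop = FALSE], y[tr], cost, epsilon, tol)
    pred <- drop(K[te, tr, drop = FALSE] %*% sol$coefs) + sol$b
    mean((y[te] - pred)^2)
  }, numeric(1))
  mean(mse)
}

#' Cross-validated mean squared error of an RBF SVR
#'
#' Seeded, shuffled k-fold partition; the returned value is the mean over
#' folds of the mean squared prediction error on held-out subjects.
#'
#' @inheritParams fit_svr
#' @param k Number of folds; default 5.
#' @param seed Master seed; the fold partition is drawn from its CV
#'   substream.
#' @return A single numeric MSE.
#' @export
cv_mse <- function(X, y, cost, gamma, epsilon = 0.1, k = 5L, seed = 1L,
                   multiplicities = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k > n) stop("cv_mse: more folds than subjects")
  if (k < 2L) stop("cv_mse: need at least 2 folds")
  Xm <- .scale_mult(X, multiplicities)
  K <- exp(-gamma * .row_dist2(Xm))
  fold_id <- .cv_folds(n, k, .sub_seed(seed, "cv_folds"))
  .cv_mse_kernel(K, y, fold_id, cost, epsilon)
}
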