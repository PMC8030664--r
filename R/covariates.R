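#' Residualize a behavioral score against covariates and scale to the unit interval
#'
#' Fits one ordinary least-squares regression of the raw score on an
#' intercept plus all covariates simultaneously, takes the residuals, and
#' min-max scales them (`(value - min) / (max - min)`) so the dependent
#' variable handed to the lesion-symptom model lies in the continuous range
#' 0-1. With no covariates the residuals are simply the mean-centered
#' scores.
#'
#' @param raw Numeric vector of raw scores, one per subject.
#' @param covariates A data.frame (or named list) of numeric covariate
#'   vectors, e.g. lesion size, an input-processing composite and the
#'   opposing working-memory score; may be `NULL` or empty.
#' @param subject_ids Optional subject identifiers.
#' @return An object of class `dependent_vector`: list with `subject_ids`,
#'   `raw`, `residual`, `scaled`, `covariates_used` and the scaling
#'   `range`.
#' @export
residualize_and_scale <- function(raw, covariates = NULL,
                                  subject_ids = NULL) {
  raw <- as.numeric(raw)
  n <- length(raw)
  if (n < 2L) stop("residualize_and_scale: need at least 2 subjects")
  if (anyNA(raw)) stop("residualize_and_scale: missing raw scores")
  subject_ids <- subject_ids %||% seq_len(n)
  covariates <- if (is.null(covariates)) list() else as.list(covariates)
  if (length(covariates) > 0 && is.null(names(covariates)))
    stop("residualize_and_scale: covariates must be named")
  X <- cbind(`(intercept)` = rep(1, n))
  for (nm in names(covariates)) {
    v <- as.numeric(covariates[[nm]])
    if (length(v) != n)
      stop(sprintf("residualize_and_scale: covariate '%s' has length %d, expected %d",
                   nm, length(v), n))
    if (anyNA(v))
      stop(sprintf("residualize_and_scale: covariate '%s' has missing values", nm))
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- nm
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[-seq_len(qx$rank)]]
    stop("residualize_and_scale: rank-deficient design; collinear covariate(s): ",
         paste(dropped, collapse = ", "))
  }
  res <- lm.fit(X, raw)$residuals
  rng <- range(res)
  if (diff(rng) < 1e-10 * max(1, max(abs(raw))))
    stop("residualize_and_scale: residuals are (numerically) constant; ",
         "cannot min-max scale")
  structure(list(
    subject_ids = subject_ids,
    raw = raw,
    residual = res,
    scaled = (res - rng[1L]) / diff(rng),
    covariates_used = names(covariates),
    range = rng
  ), class = "dependent_vector")
}

#' @export
print.dependent_vector <- function(x, ...) {
  cat(sprintf("Dependent vector: %d subjects, residualized on {%s}\n",
              length(x$raw),
              if (length(x$covariates_used)) paste(x$covariates_used, collapse = ", ")
              else "intercept only"))
  cat(sprintf("  residual range [%.4g, %.4g], scaled to [0, 1]\n",
              x$range[1L], x$range[2L]))
  invisible(x)
}

#' Screen candidate nuisance covariates against a dependent measure
#'
#' Pearson-correlates each candidate with the dependent measure and applies
#' a Bonferroni correction across candidates (`p_corrected =
#' min(1, p * n_candidates)`); candidates significant after correction are
#' flagged for inclusion in the residualization. A constant candidate has
#' undefined correlation and is reported with `NA`.
#'
#' @param dependent Numeric vector (>= 4 subjects).
#' @param candidates Data.frame or named list of numeric candidate vectors.
#' @param alpha Flagging threshold on the corrected p-value; default 0.05.
#' @return A data.frame with one row per candidate: `r`, `p`,
#'   `p_bonferroni`, `flagged`.
#' @export
screen_covariates <- function(dependent, candidates, alpha = 0.05) {
  dependent <- as.numeric(dependent)
  if (length(dependent) < 4L)
    stop("screen_covariates: need at least 4 subjects")
  candidates <- as.list(candidates)
  if (length(candidates) == 0L) stop("screen_covariates: no candidates")
  if (is.null(names(candidates)))
    stop("screen_covariates: candidates must be named")
  m <- length(candidates)
  out <- do.call(rbind, lapply(names(candidates), function(nm) {
    v <- as.numeric(candidates[[nm]])
    if (length(v) != length(dependent))
      stop(sprintf("screen_covariates: candidate '%s' length mismatch", nm))
    if (sd(v) == 0)
      return(data.frame(candidate = nm, r = NA_real_, p = NA_real_,
                        p_bonferroni = NA_real_, flagged = FALSE))
    ct <- cor.test(dependent, v, method = "pearson")
    p_adj <- min(1, ct$p.value * m)
    data.frame(candidate = nm, r = unname(ct$estimate), p = ct$p.value,
               p_bonferroni = p_adj, flagged = p_adj < alpha)
  }))
  rownames(out) <- NULL
  out
}
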