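#' Construct signal-detection trial tallies
#'
#' Hit and false-alarm counts for one foil condition of a yes/no
#' picture-word matching task: `n_match` matching trials of which `n_hits`
#' were accepted, and `n_foil` foil trials of which `n_false_alarms` were
#' (incorrectly) accepted.
#'
#' @param n_match,n_hits,n_foil,n_false_alarms Non-negative integers;
#'   `n_match` and `n_foil` must be positive.
#' @return An object of class `detection_counts`.
#' @export
detection_counts <- function(n_match, n_hits, n_foil, n_false_alarms) {
  v <- c(n_match = n_match, n_hits = n_hits, n_foil = n_foil,
         n_false_alarms = n_false_alarms)
  if (any(!is.finite(v)) || any(v < 0) || any(v != round(v)))
    stop("detection_counts: counts must be non-negative integers")
  if (n_match < 1L || n_foil < 1L)
    stop("detection_counts: zero trials in a category; d' is undefined")
  if (n_hits > n_match) stop("detection_counts: n_hits > n_match")
  if (n_false_alarms > n_foil)
    stop("detection_counts: n_false_alarms > n_foil")
  structure(as.list(setNames(as.integer(v), names(v))),
            class = "detection_counts")
}

#' Signal-detection discriminability (d-prime)
#'
#' `d' = qnorm(H) - qnorm(F)` with `H` the hit rate and `F` the false-alarm
#' rate. Extreme proportions (0 or 1) make the normal quantile infinite;
#' under the default half-trial correction a rate of 0 is replaced by
#' `1/(2N)` and a rate of 1 by `1 - 1/(2N)`, where `N` is the number of
#' trials in that category. With 17 trials per category this bounds d' at
#' `2 * qnorm(33/34) = 3.78` (2 dp), the ceiling attained by a perfect
#' scorer.
#'
#' @param counts A [detection_counts] object.
#' @param correction `"half_trial"` (default) or `"none"` (extreme rates
#'   then yield infinite d').
#' @return Numeric d' value.
#' @examples
#' score_dprime(detection_counts(17, 17, 17, 0))  # ceiling, 3.78
#' @export
score_dprime <- function(counts, correction = c("half_trial", "none")) {
  stopifnot(inherits(counts, "detection_counts"))
  correction <- match.arg(correction)
  adj <- function(x, n) {
    p <- x / n
    if (correction == "half_trial") {
      if (p == 0) p <- 1 / (2 * n)
      if (p == 1) p <- 1 - 1 / (2 * n)
    }
    p
  }
  H <- adj(counts$n_hits, counts$n_match)
  F <- adj(counts$n_false_alarms, counts$n_foil)
  qnorm(H) - qnorm(F)
}
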