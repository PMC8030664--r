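#' Span tasks and their administration bounds
#'
#' Two auditory working-memory span tasks are supported. The digit matching
#' task presents list lengths 2 to 6 (6, 8, 6, 8 and 10 trials); the
#' category probe task presents list lengths 1 to 4 (8, 8, 12 and 16
#' trials). Administration stops at the first list length scored below 75%
#' accuracy.
#'
#' @keywords internal
.span_tasks <- list(
  phonological_digit_matching = list(min_length = 2L, max_length = 6L,
                                     trials = c(6L, 8L, 6L, 8L, 10L)),
  semantic_category_probe     = list(min_length = 1L, max_length = 4L,
                                     trials = c(8L, 8L, 12L, 16L))
)

#' Construct a span accuracy curve
#'
#' Bundles one subject's per-list-length trial counts for a span task and
#' validates them: counts consistent, list lengths strictly increasing and
#' within the task's administered range.
#'
#' @param task `"phonological_digit_matching"` or `"semantic_category_probe"`.
#' @param list_length Integer vector of administered list lengths.
#' @param n_trials Integer vector, trials administered at each length.
#' @param n_correct Integer vector, trials correct at each length.
#' @return An object of class `span_curve`.
#' @examples
#' span_curve("phonological_digit_matching",
#'            list_length = 2:4, n_trials = c(6, 8, 6), n_correct = c(6, 7, 4))
#' @export
span_curve <- function(task = c("phonological_digit_matching",
                                "semantic_category_probe"),
                       list_length, n_trials, n_correct) {
  task <- match.arg(task)
  if (length(list_length) == 0L)
    stop("span_curve: empty curve (no administered list lengths)")
  if (length(n_trials) != length(list_length) ||
      length(n_correct) != length(list_length))
    stop("span_curve: list_length, n_trials, n_correct must have equal length")
  list_length <- as.integer(list_length)
  n_trials <- as.integer(n_trials)
  n_correct <- as.integer(n_correct)
  if (any(n_trials < 1L)) stop("span_curve: n_trials must be positive")
  if (any(n_correct < 0L) || any(n_correct > n_trials))
    stop("span_curve: need 0 <= n_correct <= n_trials")
  if (any(diff(list_length) <= 0L))
    stop("span_curve: list lengths must be strictly increasing")
  b <- .span_tasks[[task]]
  if (any(list_length < b$min_length) || any(list_length > b$max_length))
    stop(sprintf("span_curve: list lengths for %s must lie in %d..%d",
                 task, b$min_length, b$max_length))
  structure(list(task = task, list_length = list_length,
                 n_trials = n_trials, n_correct = n_correct),
            class = "span_curve")
}

#' @export
print.span_curve <- function(x, ...) {
  cat("Span curve (", x$task, ")\n", sep = "")
  acc <- x$n_correct / x$n_trials
  print(data.frame(list_length = x$list_length, n_trials = x$n_trials,
                   n_correct = x$n_correct, accuracy = round(acc, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Score a span curve by linear interpolation at the accuracy criterion
#'
#' The span is the list length at which accuracy crosses the criterion
#' (default 75%), found by linear interpolation between the last length at
#' or above criterion and the first below it:
#' `span = L + (acc_L - 75) / (acc_L - acc_next)` with accuracies in
#' percentage points. Edge rules: if the shortest administered length is
#' already below criterion, a virtual one-item-shorter length at 100%
#' accuracy anchors the interpolation (floor); if the longest administered
#' length is still at or above criterion, a virtual one-item-longer length
#' at 50% accuracy anchors it (ceiling). For the digit task these are the
#' 1-item/100% and 7-item/50% rules; for the category probe the same rules
#' generalize to 0-item/100% and 5-item/50%.
#'
#' The curve must honor the stop rule under which the tasks are
#' administered: every entry except the last at or above criterion, the last
#' either below criterion or at the task maximum.
#'
#' @param curve A [span_curve].
#' @param threshold Accuracy criterion as a proportion, in (0.5, 1);
#'   default 0.75.
#' @return Numeric span in items.
#' @examples
#' # printed worked example: 7/8 at length 3, 4/6 at length 4 -> 3.60
#' score_span(span_curve("phonological_digit_matching", 3:4, c(8, 6), c(7, 4)))
#' @export
score_span <- function(curve, threshold = 0.75) {
  stopifnot(inherits(curve, "span_curve"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0.5 || threshold >= 1)
    stop("score_span: threshold must be a single value in (0.5, 1)")
  b <- .span_tasks[[curve$task]]
  acc <- curve$n_correct / curve$n_trials
  k <- length(acc)
  below <- acc < threshold
  if (any(below[-k]))
    stop(sprintf(paste0("score_span: accuracy fell below criterion at list ",
                        "length %d but longer lengths were administered; ",
                        "the stop rule forbids this"),
                 curve$list_length[which(below[-k])[1L]]))
  last_len <- curve$list_length[k]
  if (!below[k] && last_len != b$max_length)
    stop(sprintf(paste0("score_span: curve ends at list length %d with ",
                        "accuracy at or above criterion; administration ",
                        "should have continued (task maximum %d)"),
                 last_len, b$max_length))
  # accuracies in percentage points, as the interpolation is stated
  th <- 100 * threshold
  accp <- 100 * acc
  if (below[1L]) {
    # floor: virtual one-shorter list at 100%
    lo_len <- curve$list_length[1L] - 1L
    lo_acc <- 100
    hi_acc <- accp[1L]
  } else if (!below[k]) {
    # ceiling: virtual one-longer list at 50%
    lo_len <- last_len
    lo_acc <- accp[k]
    hi_acc <- 50
  } else {
    lo_len <- curve$list_length[k - 1L]
    lo_acc <- accp[k - 1L]
    hi_acc <- accp[k]
  }
  den <- lo_acc - hi_acc
  if (den <= 0)
    stop(sprintf(paste0("score_span: degenerate curve at list length %d: ",
                        "equal accuracies straddle the criterion ",
                        "(zero interpolation denominator)"), lo_len))
  lo_len + (lo_acc - th) / den
}
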