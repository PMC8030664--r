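#' Read a long-format behavioral trial table
#'
#' The table (TSV) has one row per subject x task x level with columns
#' `subject_id`, `task`, `level`, `n_trials`, `n_correct`. For the span
#' tasks (`phonological_digit_matching`, `semantic_category_probe`) `level`
#' is the list length; for the `picture_word_matching` task it is one of
#' `match`, `phonological_foil`, `semantic_foil` (on foil rows `n_correct`
#' counts correct rejections).
#'
#' @param path Path to a tab-separated file.
#' @return A validated data.frame.
#' @export
read_behavior <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "task", "level", "n_trials", "n_correct")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_behavior: missing column(s): ", paste(miss, collapse = ", "))
  known <- c(names(.span_tasks), "picture_word_matching")
  bad <- setdiff(unique(df$task), known)
  if (length(bad))
    stop("read_behavior: unknown task(s): ", paste(bad, collapse = ", "))
  df
}

#' Score a behavioral trial table into per-subject measures
#'
#' Applies [score_span] to each subject's span curves and [score_dprime] to
#' the picture-word matching counts (match trials are shared between the
#' phonological and semantic foil conditions), returning one row per
#' subject.
#'
#' @param trials A trial table as returned by [read_behavior] (or built in
#'   code, e.g. by [simulate_cohort]).
#' @param threshold Span accuracy criterion, default 0.75.
#' @param correction d-prime extreme-proportion correction, default
#'   `"half_trial"`.
#' @return A data.frame with columns `subject_id`, `span_phonological`,
#'   `span_semantic`, `dprime_phonological`, `dprime_semantic` (NA where a
#'   task is absent for a subject).
#' @export
score_behavior <- function(trials, threshold = 0.75,
                           correction = "half_trial") {
  ids <- unique(trials$subject_id)
  rows <- lapply(ids, function(id) {
    tt <- trials[trials$subject_id == id, , drop = FALSE]
    span_of <- function(task) {
      st <- tt[tt$task == task, , drop = FALSE]
      if (nrow(st) == 0L) return(NA_real_)
      st <- st[order(as.integer(st$level)), , drop = FALSE]
      score_span(span_curve(task, as.integer(st$level),
                            st$n_trials, st$n_correct),
                 threshold = threshold)
    }
    dp_of <- function(cond) {
      pw <- tt[tt$task == "picture_word_matching", , drop = FALSE]
      mr <- pw[pw$level == "match", , drop = FALSE]
      fr <- pw[pw$level == cond, , drop = FALSE]
      if (nrow(mr) != 1L || nrow(fr) != 1L) return(NA_real_)
      score_dprime(detection_counts(
        n_match = mr$n_trials, n_hits = mr$n_correct,
        n_foil = fr$n_trials,
        n_false_alarms = fr$n_trials - fr$n_correct
      ), correction = correction)
    }
    data.frame(subject_id = id,
               span_phonological = span_of("phonological_digit_matching"),
               span_semantic = span_of("semantic_category_probe"),
               dprime_phonological = dp_of("phonological_foil"),
               dprime_semantic = dp_of("semantic_foil"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write per-subject scores with a JSON sidecar
#'
#' Writes the scores table as TSV and a sidecar JSON recording the scoring
#' options (span criterion, d-prime correction) and, when supplied, the
#' covariates and min-max ranges used for each dependent variable.
#'
#' @param scores Data.frame of per-subject scores.
#' @param path Output TSV path; the sidecar is written next to it with a
#'   `.json` extension.
#' @param meta Named list of scoring/residualization metadata.
#' @return Invisibly, the sidecar path.
#' @export
write_scores <- function(scores, path, meta = list()) {
  write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- sub("\\.[^.]+$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(sidecar)
}
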