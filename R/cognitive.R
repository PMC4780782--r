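#' Norm-referenced Z-score
#'
#' `(value - mean) / sd` against a reference population. For reverse-scored
#' tasks (times, where larger raw values mean worse performance) the
#' deficit-oriented Z-score is `(mean - value) / sd`, so that negative Z
#' always means impaired.
#'
#' @param value raw score(s).
#' @param mean,sd reference mean and standard deviation (`sd > 0`).
#' @param reverse logical; `TRUE` for time scores.
#' @return Numeric Z-score(s).
#' @export
zscore <- function(value, mean, sd, reverse = FALSE) {
  if (any(sd <= 0)) stop("norm sd must be > 0")
  z <- (value - mean) / sd
  if (reverse) -z else z
}

#' Phoneme-awareness norms from the current control group
#'
#' The PA tasks are normed on the study's own control children (mean and
#' SD of each task), mirroring the practice of computing PA Z-scores from
#' a concurrent control sample rather than external norms.
#'
#' @param controls participant table restricted to controls, with columns
#'   `deletion`, `segmentation`, `acronyms`.
#' @return A norm table (`task`, `mean`, `sd`, `reverse`).
#' @export
pa_norms_from_controls <- function(controls) {
  tasks <- c("deletion", "segmentation", "acronyms")
  missing_cols <- setdiff(tasks, names(controls))
  if (length(missing_cols) > 0L)
    stop("missing PA task column(s): ", paste(missing_cols, collapse = ", "))
  data.frame(task = tasks,
             mean = vapply(tasks, function(t) mean(controls[[t]]), 0),
             sd = vapply(tasks, function(t) sd(controls[[t]]), 0),
             reverse = FALSE, row.names = NULL)
}

# Column sets used by composites() and the Z-profile.
pa_tasks <- c("deletion", "segmentation", "acronyms")
report_tasks <- c("global_report", "partial_report")
reading_acc_tasks <- c("rw_score", "iw_score", "pw_score")
reading_time_tasks <- c("rw_time", "iw_time", "pw_time")

#' Z-profile and composite scores
#'
#' Computes, per participant: deficit-oriented Z-scores for every task
#' (PA tasks against the control-group norms, reading and report tasks
#' against the reference norm table, times reverse-scored) and the four
#' composites:
#' \itemize{
#'   \item `pa_composite`: mean accuracy percentage of the three PA tasks;
#'   \item `vas_composite`: mean percentage of global (max 100) and
#'     partial (max 50) report;
#'   \item `reading_accuracy`: mean percentage of the three /20 reading
#'     scores;
#'   \item `reading_speed`: mean of the three time Z-scores on the raw
#'     scale (larger = slower), so speed correlates negatively with
#'     reading ability.
#' }
#'
#' @param participants participant table (one row per child) with all task
#'   columns.
#' @param norms reference norm table ([default_norms()]) for reading and
#'   VA span.
#' @param pa_norms PA norm table, typically
#'   [pa_norms_from_controls()] of the same cohort's controls.
#' @return A data frame of class `"zprofile"`, one row per participant:
#'   `z_<task>` columns and the four composites.
#' @export
composites <- function(participants, norms = default_norms(),
                       pa_norms = pa_norms_from_controls(
                         participants[!participants$dyslexic, ])) {
  all_tasks <- c(pa_tasks, report_tasks, reading_acc_tasks, reading_time_tasks)
  missing_cols <- setdiff(all_tasks, names(participants))
  if (length(missing_cols) > 0L)
    stop("missing task column(s): ", paste(missing_cols, collapse = ", "))
  norm_row <- function(task) {
    src <- if (task %in% pa_tasks) pa_norms else norms
    r <- src[src$task == task, , drop = FALSE]
    if (nrow(r) != 1L) stop("no norm entry for task: ", task)
    r
  }
  out <- participants[, intersect(c("participant_id", "group", "dyslexic",
                                    "age_months"), names(participants)),
                      drop = FALSE]
  for (task in all_tasks) {
    r <- norm_row(task)
    out[[paste0("z_", task)]] <- zscore(participants[[task]], r$mean, r$sd,
                                        reverse = isTRUE(r$reverse[1]))
  }
  out$pa_composite <- rowMeans(participants[, pa_tasks])
  out$vas_composite <- (participants$global_report +
                          participants$partial_report / 50 * 100) / 2
  out$reading_accuracy <- rowMeans(participants[, reading_acc_tasks] / 20 * 100)
  # raw-scale time Z (larger = slower), not the deficit-oriented sign
  time_z <- vapply(reading_time_tasks, function(task) {
    r <- norm_row(task)
    (participants[[task]] - r$mean) / r$sd
  }, numeric(nrow(participants)))
  out$reading_speed <- rowMeans(matrix(time_z, nrow = nrow(participants)))
  structure(out, class = c("zprofile", "data.frame"))
}

#' Single-letter control exclusion rule
#'
#' A child is excluded from VA-span analyses when the maximal score of 10
#' correct identifications is not reached at one of the presentation
#' durations.
#'
#' @param letter_scores numeric vector (or one-row data frame of
#'   `letter_id_*` columns) of per-duration scores out of 10.
#' @return `TRUE` when the child should be excluded.
#' @export
letter_control_exclusion <- function(letter_scores) {
  x <- unlist(letter_scores, use.names = FALSE)
  if (length(x) == 0L || anyNA(x)) stop("per-duration letter scores required")
  any(x < 10)
}
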