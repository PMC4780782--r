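#' Deficit classification of dyslexic participants
#'
#' A child is phonologically impaired when any of the three PA task
#' Z-scores is strictly below -1.5, and VA-span impaired when any of the
#' two report-task Z-scores is strictly below -1.5. The 2x2 of these flags
#' gives one of four labels: `"PA_only"`, `"VAS_only"`, `"double"`,
#' `"none"`.
#'
#' @param z_pa numeric vector (or matrix/data frame rows) of the three PA
#'   task Z-scores.
#' @param z_report the two report-task Z-scores.
#' @param threshold deficit cutoff (default -1.5, strict inequality).
#' @return A character label (vectorized over rows when matrices are
#'   given).
#' @export
classify_deficit <- function(z_pa, z_report, threshold = -1.5) {
  z_pa <- rbind(z_pa); z_report <- rbind(z_report)
  if (ncol(z_pa) != 3L || ncol(z_report) != 2L)
    stop("expected 3 PA and 2 report Z-scores")
  if (anyNA(z_pa) || anyNA(z_report)) stop("missing Z-scores")
  pa_imp <- apply(z_pa < threshold, 1L, any)
  vas_imp <- apply(z_report < threshold, 1L, any)
  unname(ifelse(pa_imp & vas_imp, "double",
                ifelse(pa_imp, "PA_only", ifelse(vas_imp, "VAS_only", "none"))))
}

#' Deficit labels for a Z-profile table
#'
#' Applies [classify_deficit()] to the dyslexic rows of a [composites()]
#' table; controls get label `"control"`.
#'
#' @param zprofiles a `"zprofile"` data frame.
#' @param threshold deficit cutoff.
#' @return The input with a `deficit_label` column appended.
#' @export
label_subgroups <- function(zprofiles, threshold = -1.5) {
  z_pa <- as.matrix(zprofiles[, paste0("z_", pa_tasks)])
  z_rep <- as.matrix(zprofiles[, paste0("z_", report_tasks)])
  lab <- classify_deficit(z_pa, z_rep, threshold)
  zprofiles$deficit_label <- ifelse(zprofiles$dyslexic, lab, "control")
  zprofiles
}

#' Age-match a control group to a dyslexic group
#'
#' Iteratively removes the single youngest control child (ties broken by
#' identifier) and recomputes a one-way ANOVA on age between the two
#' groups, until the group difference is non-significant (`p >= alpha`) or
#' the control group would fall below a floor. Mirrors the practice of
#' excluding the youngest controls to match an older dyslexic subgroup.
#'
#' @param dys_ages ages (months) of the dyslexic group.
#' @param control_ages ages (months) of the candidate controls.
#' @param control_ids identifiers for the controls (used for deterministic
#'   tie-breaking and to report the retained subset).
#' @param alpha stop rule: matching succeeds when the ANOVA p-value is at
#'   least `alpha` (default 0.10).
#' @param min_controls smallest admissible control group (default twice
#'   the dyslexic group size, floored at 2).
#' @return A list: `kept_ids`, `n_removed`, `p_final`, `removed_ids`.
#' @export
age_match_controls <- function(dys_ages, control_ages,
                               control_ids = seq_along(control_ages),
                               alpha = 0.10,
                               min_controls = max(2L, 2L * length(dys_ages))) {
  if (length(dys_ages) == 0L || length(control_ages) == 0L)
    stop("both groups must be non-empty")
  if (length(control_ids) != length(control_ages))
    stop("control_ids must match control_ages")
  keep <- order(control_ages, as.character(control_ids))  # removal queue: youngest first
  ctrl <- data.frame(id = as.character(control_ids), age = control_ages,
                     stringsAsFactors = FALSE)[keep, ]
  removed <- character(0)
  repeat {
    p <- suppressWarnings(anova(lm(age ~ grp, data = data.frame(
      age = c(dys_ages, ctrl$age),
      grp = rep(c("dys", "ctl"),
                c(length(dys_ages), nrow(ctrl))))))[["Pr(>F)"]][1])
    if (is.na(p)) p <- 1  # no age variance at all: trivially matched
    if (p >= alpha)
      return(list(kept_ids = sort(ctrl$id), n_removed = length(removed),
                  p_final = p, removed_ids = removed))
    if (nrow(ctrl) - 1L < min_controls)
      stop("age matching failed: p = ", signif(p, 3), " with ", nrow(ctrl),
           " controls left (floor ", min_controls, "); groups cannot be matched")
    removed <- c(removed, ctrl$id[1])
    ctrl <- ctrl[-1L, , drop = FALSE]
  }
}
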