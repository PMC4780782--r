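# Schema checks for externally supplied trial files. Reports offending
# data rows (1-based, excluding the header) by number.
check_schema <- function(df, schema, file_label) {
  missing_cols <- setdiff(names(schema), names(df))
  if (length(missing_cols) > 0L)
    stop(file_label, ": missing column(s): ", paste(missing_cols, collapse = ", "))
  for (col in names(schema)) {
    allowed <- schema[[col]]
    if (is.null(allowed)) next
    bad <- which(!df[[col]] %in% allowed)
    if (length(bad) > 0L)
      stop(file_label, ": invalid values in column '", col, "' at row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "),
           if (length(bad) > 5L) " ..." else "")
  }
  invisible(TRUE)
}

write_csv_plain <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
}

# Scoring + analysis stages shared by run_study() and score_only().
analyze_cohort <- function(participants, identification, discrimination,
                           norms = default_norms(), continuum = vot_continuum(),
                           matching_alpha = 0.10, alpha = 0.05,
                           log_lines = NULL) {
  logf <- function(...) {
    if (!is.null(log_lines)) log_lines(paste0(...))
    invisible(NULL)
  }
  cp <- score_participants(identification, discrimination, continuum)
  logf("scored ", nrow(cp), " participants; boundary converged for ",
       sum(cp$boundary_converged))
  merged <- merge(participants, cp, by = "participant_id", sort = TRUE)

  zp <- composites(merged, norms)
  zp <- label_subgroups(zp)
  merged <- merge(merged, zp[, c("participant_id", "deficit_label",
                                 "pa_composite", "vas_composite",
                                 "reading_accuracy", "reading_speed")],
                  by = "participant_id", sort = TRUE)
  logf("subgroup counts: ",
       paste(names(table(zp$deficit_label[zp$dyslexic])),
             table(zp$deficit_label[zp$dyslexic]), sep = "=", collapse = ", "))

  # group ANOVA on d' at the three interior pair centers, Task x VOT within
  centers <- c("m30", "0", "30")
  long <- do.call(rbind, lapply(centers, function(ct) {
    rbind(data.frame(participant = merged$participant_id,
                     group = ifelse(merged$dyslexic, "DYS", "CTL"),
                     task = "observed", vot = ct,
                     dprime = merged[[paste0("obs_d_", ct)]]),
          data.frame(participant = merged$participant_id,
                     group = ifelse(merged$dyslexic, "DYS", "CTL"),
                     task = "predicted", vot = ct,
                     dprime = merged[[paste0("pred_d_", ct)]]))
  }))
  anova_res <- if (length(unique(long$group)) == 2L)
    mixed_anova(long) else NULL
  if (!is.null(anova_res)) logf(format_anova(anova_res))

  ancova_res <- if (length(unique(merged$dyslexic)) == 2L)
    ancova_peak(data.frame(peak_amplitude = merged$pred_peak_amplitude,
                           group = ifelse(merged$dyslexic, "DYS", "CTL"),
                           peak_location = merged$pred_peak_center)) else NULL

  dys <- merged[merged$dyslexic, ]
  corr_vars <- c("reading_accuracy", "reading_speed", "vas_composite",
                 "pa_composite", "pred_peak_amplitude")
  corr_res <- if (nrow(dys) >= 5L)
    partial_correlation_table(dys, corr_vars) else NULL

  scan <- if (nrow(dys) >= 7L)
    scan_cp_candidates(dys, c("pred_peak_amplitude", "obs_peak_amplitude",
                              "pred_d_0", "obs_d_0")) else NULL
  med <- if (nrow(dys) > 7L) causal_steps(dys) else NULL
  if (!is.null(med))
    logf("mediation: Sobel z = ", sprintf("%.3f", med$sobel_z),
         ", one-sided p = ", sprintf("%.4f", med$sobel_p_one_sided),
         ", steps passed = ", sum(med$steps), "/4")

  list(cp = cp, zprofiles = zp, merged = merged, anova = anova_res,
       ancova = ancova_res, correlations = corr_res, cp_scan = scan,
       mediation = med)
}

write_analysis_outputs <- function(res, out_dir) {
  write_csv_plain(res$cp, file.path(out_dir, "cp_derived.csv"))
  write_csv_plain(res$zprofiles, file.path(out_dir, "zprofiles.csv"))
  sub <- res$zprofiles[, c("participant_id", "deficit_label")]
  write_csv_plain(sub, file.path(out_dir, "subgroups.csv"))
  if (!is.null(res$anova))
    write_csv_plain(rbind(res$anova, res$ancova),
                    file.path(out_dir, "anova_results.csv"))
  if (!is.null(res$correlations))
    write_csv_plain(res$correlations, file.path(out_dir, "correlations.csv"))
  if (!is.null(res$mediation)) {
    m <- res$mediation
    jsonlite::write_json(
      list(paths = as.data.frame(m$paths), sobel_z = m$sobel_z,
           sobel_p_one_sided = m$sobel_p_one_sided,
           steps = as.list(m$steps), mediated = m$mediated, n = m$n),
      file.path(out_dir, "mediation.json"),
      digits = NA, auto_unbox = TRUE)
  }
  invisible(NULL)
}

#' Run the full simulated study
#'
#' Simulate a cohort from a config, score it, build Z-profiles and
#' subgroups, run the group analyses and the mediation, and write every
#' stage to fixed file contracts under `out_dir`: `participants.csv`,
#' `identification_trials.csv`, `discrimination_trials.csv`,
#' `cp_derived.csv`, `zprofiles.csv`, `subgroups.csv`,
#' `anova_results.csv`, `correlations.csv`, `mediation.json`,
#' `config.json` and `run.log`. The run is a pure function of the config;
#' partial outputs are removed on failure.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory (created if needed).
#' @param matching_alpha,alpha analysis switches (age-matching stop rule,
#'   significance level).
#' @return Invisibly, the analysis result list (see the elements written
#'   above plus the in-memory tables).
#' @export
run_study <- function(config = cohort_config(), out_dir,
                      matching_alpha = 0.10, alpha = 0.05) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  created <- character(0)
  log_buf <- character(0)
  logf <- function(line) log_buf <<- c(log_buf, line)
  ok <- FALSE
  on.exit({
    if (!ok) unlink(file.path(out_dir, created))
  })
  logf(paste0("votcp ", as.character(utils::packageVersion("votcp")),
              " | R ", paste(R.version$major, R.version$minor, sep = "."),
              " | seed ", config$seed))

  cohort <- simulate_cohort(config)
  n_dys <- sum(cohort$participants$dyslexic)
  write_csv_plain(cohort$participants, file.path(out_dir, "participants.csv"))
  write_csv_plain(cohort$identification,
                  file.path(out_dir, "identification_trials.csv"))
  write_csv_plain(cohort$discrimination,
                  file.path(out_dir, "discrimination_trials.csv"))
  write_cohort_config(config, file.path(out_dir, "config.json"))
  created <- c("participants.csv", "identification_trials.csv",
               "discrimination_trials.csv", "config.json")
  logf(paste0("simulated ", nrow(cohort$participants), " children (",
              n_dys, " dyslexic)"))

  if (n_dys == 0L || n_dys == nrow(cohort$participants)) {
    res <- list(cp = score_participants(cohort$identification,
                                        cohort$discrimination))
    write_csv_plain(res$cp, file.path(out_dir, "cp_derived.csv"))
    created <- c(created, "cp_derived.csv")
    logf("single-group cohort: stopped after CP scoring (group analyses need both groups)")
    writeLines(log_buf, file.path(out_dir, "run.log"))
    ok <- TRUE
    message("run_study: single-group cohort; stopped after scoring")
    return(invisible(res))
  }

  res <- analyze_cohort(cohort$participants, cohort$identification,
                        cohort$discrimination, norms = config$norms,
                        matching_alpha = matching_alpha, alpha = alpha,
                        log_lines = logf)
  write_analysis_outputs(res, out_dir)
  created <- c(created, "cp_derived.csv", "zprofiles.csv", "subgroups.csv",
               "anova_results.csv", "correlations.csv", "mediation.json")
  writeLines(log_buf, file.path(out_dir, "run.log"))
  ok <- TRUE
  invisible(res)
}

#' Score and analyze externally supplied trial data
#'
#' Applies the scoring, Z-profiling and analysis stages to trial-level
#' files produced outside the simulator (or by it: scoring the
#' simulator's own output reproduces the integrated run). Inputs are
#' validated against the file contracts; violations are reported with row
#' numbers, and trials for unknown participants are listed.
#'
#' @param participants_file CSV with one row per child (id, group or
#'   dyslexic flag, age, task scores).
#' @param identification_file CSV `participant_id, trial, vot_ms,
#'   response` with response in `d`/`t`.
#' @param discrimination_file CSV `participant_id, trial, vot_a_ms,
#'   vot_b_ms, response` with response in `same`/`different`.
#' @param out_dir output directory for the derived tables.
#' @param norms reference norm table.
#' @return Invisibly, the analysis result list.
#' @export
score_only <- function(participants_file, identification_file,
                       discrimination_file, out_dir,
                       norms = default_norms()) {
  participants <- read.csv(participants_file, stringsAsFactors = FALSE)
  idt <- read.csv(identification_file, stringsAsFactors = FALSE)
  dit <- read.csv(discrimination_file, stringsAsFactors = FALSE)
  check_schema(participants, list(participant_id = NULL, age_months = NULL),
               basename(participants_file))
  if (!"dyslexic" %in% names(participants)) {
    if (!"group" %in% names(participants))
      stop(basename(participants_file),
           ": needs a 'dyslexic' or 'group' column")
    participants$dyslexic <- participants$group != "control"
  }
  check_schema(idt, list(participant_id = NULL, vot_ms = NULL,
                         response = c("d", "t")),
               basename(identification_file))
  check_schema(dit, list(participant_id = NULL, vot_a_ms = NULL,
                         vot_b_ms = NULL, response = c("same", "different")),
               basename(discrimination_file))
  known <- participants$participant_id
  orphans <- setdiff(union(idt$participant_id, dit$participant_id), known)
  if (length(orphans) > 0L)
    stop("trials for unknown participant id(s): ",
         paste(orphans, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- analyze_cohort(participants, idt, dit, norms = norms)
  write_analysis_outputs(res, out_dir)
  invisible(res)
}
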