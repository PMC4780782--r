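#' Default norm table for task scores
#'
#' Reference means and standard deviations used to (a) anchor the affine
#' latent-to-score maps of the simulator and (b) compute norm-referenced
#' Z-scores for reading and VA span. They are synthetic norms on the tasks'
#' printed scales, chosen as plausible control-population values; the
#' phoneme-awareness tasks are instead normed on the current control group
#' at analysis time (see [pa_norms_from_controls()]).
#'
#' `reverse = TRUE` marks time scores, for which a deficit corresponds to a
#' larger raw value; their deficit Z-score is `(mean - value)/sd`.
#'
#' @return A data frame with columns `task`, `mean`, `sd`, `min`, `max`,
#'   `reverse`, `source`.
#' @export
default_norms <- function() {
  d <- rbind(
    data.frame(task = "deletion",      mean = 83.4, sd = 15.3, min = 0, max = 100, reverse = FALSE),
    data.frame(task = "segmentation",  mean = 60.8, sd = 25.0, min = 0, max = 100, reverse = FALSE),
    data.frame(task = "acronyms",      mean = 82.0, sd = 20.0, min = 0, max = 100, reverse = FALSE),
    data.frame(task = "global_report", mean = 83.3, sd = 11.0, min = 0, max = 100, reverse = FALSE),
    data.frame(task = "partial_report", mean = 43.6, sd = 5.2, min = 0, max = 50, reverse = FALSE),
    data.frame(task = "rw_score",      mean = 19.1, sd = 1.4,  min = 0, max = 20, reverse = FALSE),
    data.frame(task = "iw_score",      mean = 16.9, sd = 2.9,  min = 0, max = 20, reverse = FALSE),
    data.frame(task = "pw_score",      mean = 17.3, sd = 2.3,  min = 0, max = 20, reverse = FALSE),
    data.frame(task = "rw_time",       mean = 27.8, sd = 6.0,  min = 5, max = 180, reverse = TRUE),
    data.frame(task = "iw_time",       mean = 30.7, sd = 8.0,  min = 5, max = 180, reverse = TRUE),
    data.frame(task = "pw_time",       mean = 34.7, sd = 9.0,  min = 5, max = 180, reverse = TRUE))
  d$source <- "synthetic control norms"
  d
}

#' Configuration of a synthetic cohort
#'
#' Generative parameters for a cohort of simulated children: group sizes,
#' ages, the identification model (participant boundary and precision),
#' the same-different response model (maximal discriminability, allophonic
#' sensitivity, response criterion), and the standardized path coefficients
#' of the planted trait structure
#' \deqn{PA = a \cdot CP + e_1, \quad
#'       ReadAcc = b \cdot PA + c' \cdot CP + d \cdot VAS + e_2, \quad
#'       ReadSpeed = d_s \cdot VAS + e_3,}
#' where CP is the standardized (negated) identification precision, so that
#' sharper identification means better CP. Reading speed loads on VA span
#' but not on phoneme awareness.
#'
#' Group structure: `dys_pa` children have identification precision shifted
#' worse by `precision_shift_pa_ms` with VA span untouched; `dys_vas`
#' children have `vas_ability` shifted by `vas_shift_sd` with precision
#' untouched; `dys_other` and `control` children are unshifted on both.
#'
#' @param n_control,n_dys_pa,n_dys_vas,n_dys_other group sizes (defaults
#'   63 controls and 17 + 20 + 26 dyslexic children).
#' @param age_mean_months,age_sd_months named per-group normal age
#'   parameters (months).
#' @param age_range_months clipping interval for ages.
#' @param boundary_mean_ms,boundary_sd_ms distribution of the latent
#'   identification boundary (ms VOT).
#' @param precision_mean_ms,precision_sd_ms distribution of the logistic
#'   identification scale (ms; smaller = sharper); truncated below at
#'   `precision_floor_ms`.
#' @param precision_shift_pa_ms worsening of precision in the `dys_pa`
#'   group (ms).
#' @param vas_shift_sd shift of `vas_ability` in the `dys_vas` group
#'   (standard deviations, negative = deficit).
#' @param d_max maximal true discriminability between unambiguous category
#'   exemplars (d-prime units).
#' @param allophonic_weight amplitude of the allophonic discriminability
#'   bumps at +/-30 ms pair centers (d-prime units; 0 disables them).
#' @param allophonic_width_ms width of the allophonic bumps.
#' @param criterion_c same-different response criterion (higher = more
#'   conservative, fewer "different" responses).
#' @param path_a,path_b,path_c_prime,path_d,path_d_speed standardized path
#'   coefficients of the trait model above.
#' @param noise_sds standard deviations of the latent disturbances
#'   (`pa`, `reading_acc`, `reading_speed`).
#' @param task_noise_sds per-task measurement noise, in norm-SD units, for
#'   the PA, report, reading-accuracy and reading-time tasks.
#' @param norms norm table as in [default_norms()].
#' @param seed master seed; the whole cohort is a pure function of the
#'   config.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_control = 63L, n_dys_pa = 17L, n_dys_vas = 20L,
                          n_dys_other = 26L,
                          age_mean_months = c(control = 121, dys_pa = 130,
                                              dys_vas = 120, dys_other = 126),
                          age_sd_months = c(control = 11, dys_pa = 15.4,
                                            dys_vas = 15.2, dys_other = 15),
                          age_range_months = c(94, 153),
                          boundary_mean_ms = 5, boundary_sd_ms = 12,
                          precision_mean_ms = 8, precision_sd_ms = 2,
                          precision_floor_ms = 1,
                          precision_shift_pa_ms = 6,
                          vas_shift_sd = -1.8,
                          d_max = 3.5,
                          allophonic_weight = 0,
                          allophonic_width_ms = 10,
                          criterion_c = 0.5,
                          path_a = 0.4, path_b = 0.4, path_c_prime = 0.1,
                          path_d = 0.35, path_d_speed = 0.45,
                          noise_sds = c(pa = 0.6, reading_acc = 0.6,
                                        reading_speed = 0.6),
                          task_noise_sds = c(pa = 0.8, report = 0.82,
                                             reading_acc = 0.6,
                                             reading_time = 0.55),
                          norms = default_norms(),
                          seed = 0L) {
  counts <- c(n_control, n_dys_pa, n_dys_vas, n_dys_other)
  if (any(counts < 0L)) stop("group counts must be >= 0")
  if (boundary_sd_ms <= 0 || precision_sd_ms <= 0) stop("sds must be > 0")
  if (any(noise_sds <= 0) || any(task_noise_sds <= 0)) stop("sds must be > 0")
  if (allophonic_weight < 0) stop("allophonic_weight must be >= 0")
  cfg <- list(n_control = as.integer(n_control), n_dys_pa = as.integer(n_dys_pa),
              n_dys_vas = as.integer(n_dys_vas), n_dys_other = as.integer(n_dys_other),
              age_mean_months = age_mean_months, age_sd_months = age_sd_months,
              age_range_months = age_range_months,
              boundary_mean_ms = boundary_mean_ms, boundary_sd_ms = boundary_sd_ms,
              precision_mean_ms = precision_mean_ms, precision_sd_ms = precision_sd_ms,
              precision_floor_ms = precision_floor_ms,
              precision_shift_pa_ms = precision_shift_pa_ms,
              vas_shift_sd = vas_shift_sd,
              d_max = d_max, allophonic_weight = allophonic_weight,
              allophonic_width_ms = allophonic_width_ms,
              criterion_c = criterion_c,
              path_a = path_a, path_b = path_b, path_c_prime = path_c_prime,
              path_d = path_d, path_d_speed = path_d_speed,
              noise_sds = noise_sds, task_noise_sds = task_noise_sds,
              norms = norms, seed = as.integer(seed))
  structure(cfg, class = "cohort_config")
}

#' Serialize / restore a cohort configuration
#'
#' A config round-trips losslessly through its JSON form, which is also the
#' form echoed into run logs.
#' @param config a [cohort_config()].
#' @param path file path; for `read_cohort_config`, a file written by
#'   `write_cohort_config`.
#' @return `read_cohort_config` returns a `"cohort_config"`.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  x <- unclass(config)
  # named vectors become JSON objects so their names survive the round trip
  named <- c("age_mean_months", "age_sd_months", "noise_sds", "task_noise_sds")
  x[named] <- lapply(x[named], as.list)
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$norms <- as.data.frame(x$norms)
  x$age_mean_months <- unlist(x$age_mean_months)
  x$age_sd_months <- unlist(x$age_sd_months)
  x$noise_sds <- unlist(x$noise_sds)
  x$task_noise_sds <- unlist(x$task_noise_sds)
  do.call(cohort_config, x[setdiff(names(x), character())])
}

#' Generate latent participant profiles
#'
#' Draws one latent profile per child: group, age, identification boundary
#' and precision, and the standardized traits (`pa_ability`,
#' `vas_ability`, `reading_acc_latent`, `reading_speed_latent`) tied
#' together by the config's path coefficients. The CP trait entering the
#' paths is `cp_std`, the negated precision standardized against the
#' control-population generative parameters, so larger = sharper
#' identification.
#'
#' @param config a [cohort_config()].
#' @return A data frame of class `"latent_profiles"`, one row per child.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- rep(c("control", "dys_pa", "dys_vas", "dys_other"),
                times = c(config$n_control, config$n_dys_pa,
                          config$n_dys_vas, config$n_dys_other))
  n <- length(groups)
  if (n == 0L) stop("empty cohort")
  with_seed(config$seed, {
    age <- config$age_mean_months[groups] +
      config$age_sd_months[groups] * rnorm(n)
    age <- pmin(pmax(age, config$age_range_months[1]), config$age_range_months[2])
    boundary <- config$boundary_mean_ms + config$boundary_sd_ms * rnorm(n)
    precision <- config$precision_mean_ms + config$precision_sd_ms * rnorm(n)
    precision <- precision + ifelse(groups == "dys_pa",
                                    config$precision_shift_pa_ms, 0)
    precision <- pmax(precision, config$precision_floor_ms)
    cp_std <- (config$precision_mean_ms - precision) / config$precision_sd_ms
    pa <- config$path_a * cp_std + config$noise_sds[["pa"]] * rnorm(n)
    vas <- rnorm(n) + ifelse(groups == "dys_vas", config$vas_shift_sd, 0)
    racc <- config$path_b * pa + config$path_c_prime * cp_std +
      config$path_d * vas + config$noise_sds[["reading_acc"]] * rnorm(n)
    rspeed <- config$path_d_speed * vas +
      config$noise_sds[["reading_speed"]] * rnorm(n)
    out <- data.frame(
      participant_id = sprintf("P%03d", seq_len(n)),
      group = groups,
      dyslexic = groups != "control",
      age_months = round(age, 1),
      boundary_mu_ms = boundary,
      precision_s_ms = precision,
      cp_std = cp_std,
      pa_ability = pa,
      vas_ability = vas,
      reading_acc_latent = racc,
      reading_speed_latent = rspeed)
    structure(out, class = c("latent_profiles", "data.frame"))
  })
}

# P(/t/ | VOT) for one participant: logistic in VOT.
p_t_label <- function(vot_ms, boundary_mu_ms, precision_s_ms) {
  if (any(precision_s_ms <= 0)) stop("precision_s_ms must be > 0")
  stats::plogis((vot_ms - boundary_mu_ms) / precision_s_ms)
}

#' Simulate identification responses
#'
#' Each trial's response is Bernoulli with
#' `P(/t/) = logistic((VOT - boundary) / precision)`.
#'
#' @param profile one row of [generate_cohort()] output (or any list with
#'   `boundary_mu_ms` and `precision_s_ms`).
#' @param design an [identification_design()].
#' @param seed integer seed.
#' @return A data frame `trial`, `vot_ms`, `response` (`"d"`/`"t"`).
#' @export
simulate_identification <- function(profile, design, seed = 0L) {
  stopifnot(inherits(design, "identification_design"))
  p <- p_t_label(design$vot_ms, profile$boundary_mu_ms, profile$precision_s_ms)
  resp <- with_seed(seed, rbinom(length(p), 1L, p))
  data.frame(trial = design$trial, vot_ms = design$vot_ms,
             response = ifelse(resp == 1L, "t", "d"))
}

# True discriminability of a pair under the generative model: a phonemic
# component proportional to the labeling-probability difference plus
# optional allophonic bumps at pair centers +/-30 ms.
d_true_pair <- function(vot_a, vot_b, profile, config) {
  pa <- p_t_label(vot_a, profile$boundary_mu_ms, profile$precision_s_ms)
  pb <- p_t_label(vot_b, profile$boundary_mu_ms, profile$precision_s_ms)
  center <- (vot_a + vot_b) / 2
  w <- config$allophonic_width_ms
  allo <- config$allophonic_weight *
    (exp(-(center + 30)^2 / (2 * w^2)) + exp(-(center - 30)^2 / (2 * w^2)))
  ifelse(vot_a == vot_b, 0, config$d_max * abs(pa - pb) + allo)
}

#' Simulate same-different discrimination responses
#'
#' Yes-no signal-detection responding on the true pair discriminability:
#' `P("different") = Phi(d_true / sqrt(2) - c)` with a single criterion
#' `c`; identical pairs have `d_true = 0`.
#'
#' @inheritParams simulate_identification
#' @param design a [discrimination_design()].
#' @param config the [cohort_config()] (supplies `d_max`,
#'   `allophonic_weight`, `criterion_c`).
#' @return A data frame `trial`, `vot_a_ms`, `vot_b_ms`, `response`
#'   (`"same"`/`"different"`).
#' @export
simulate_discrimination <- function(profile, design, config, seed = 0L) {
  stopifnot(inherits(design, "discrimination_design"))
  d <- d_true_pair(design$vot_a_ms, design$vot_b_ms, profile, config)
  p_diff <- pnorm(d / sqrt(2) - config$criterion_c)
  resp <- with_seed(seed, rbinom(length(p_diff), 1L, p_diff))
  data.frame(trial = design$trial, vot_a_ms = design$vot_a_ms,
             vot_b_ms = design$vot_b_ms,
             response = ifelse(resp == 1L, "different", "same"))
}

# Clip to a task's printed range.
clip_score <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulate cognitive task scores for one child
#'
#' Maps latent traits to the tasks' printed score scales by affine
#' transforms anchored on the norm table (`score = mean + sd * (trait +
#' task noise)`), clipped to each task's range. Time scores are reversed:
#' a larger `reading_speed_latent` (faster reader) gives smaller times.
#' Single-letter identification scores are Binomial(10) per duration with
#' accuracy increasing in duration.
#'
#' @inheritParams simulate_discrimination
#' @param norms norm table as in [default_norms()].
#' @return A one-row data frame with all task scores on their printed
#'   scales.
#' @export
simulate_task_scores <- function(profile, norms = default_norms(),
                                 config = cohort_config(), seed = 0L) {
  nm <- function(task) norms[norms$task == task, , drop = FALSE]
  tn <- config$task_noise_sds
  with_seed(seed, {
    draw <- function(task, trait, noise_sd, reverse = FALSE) {
      r <- nm(task)
      lat <- if (reverse) -(trait + noise_sd * rnorm(1)) else
        trait + noise_sd * rnorm(1)
      clip_score(r$mean + r$sd * lat, r$min, r$max)
    }
    dur <- c(33L, 50L, 67L, 84L, 101L)
    p_letter <- stats::plogis(2.5 + 0.012 * (dur - 67))
    letter_scores <- rbinom(5L, 10L, p_letter)
    data.frame(
      participant_id = profile$participant_id,
      deletion = draw("deletion", profile$pa_ability, tn[["pa"]]),
      segmentation = draw("segmentation", profile$pa_ability, tn[["pa"]]),
      acronyms = draw("acronyms", profile$pa_ability, tn[["pa"]]),
      global_report = draw("global_report", profile$vas_ability, tn[["report"]]),
      partial_report = draw("partial_report", profile$vas_ability, tn[["report"]]),
      rw_score = draw("rw_score", profile$reading_acc_latent, tn[["reading_acc"]]),
      iw_score = draw("iw_score", profile$reading_acc_latent, tn[["reading_acc"]]),
      pw_score = draw("pw_score", profile$reading_acc_latent, tn[["reading_acc"]]),
      rw_time = draw("rw_time", profile$reading_speed_latent, tn[["reading_time"]], reverse = TRUE),
      iw_time = draw("iw_time", profile$reading_speed_latent, tn[["reading_time"]], reverse = TRUE),
      pw_time = draw("pw_time", profile$reading_speed_latent, tn[["reading_time"]], reverse = TRUE),
      letter_id_33 = letter_scores[1], letter_id_50 = letter_scores[2],
      letter_id_67 = letter_scores[3], letter_id_84 = letter_scores[4],
      letter_id_101 = letter_scores[5])
  })
}

#' Simulate a full cohort with trial-level data
#'
#' Generates the latent profiles and, per child, an identification block,
#' a discrimination block and all task scores. The whole result is a pure
#' function of the config (per-child seeds are derived from the master
#' seed).
#'
#' @param config a [cohort_config()].
#' @param id_design,disc_design the trial designs administered to every
#'   child (defaults: the standard 60- and 80-trial blocks).
#' @return A list of class `"cohort_data"` with elements `profiles`,
#'   `participants` (task scores merged with id, group, age),
#'   `identification` and `discrimination` (trial tables with
#'   `participant_id`), and `config`.
#' @export
simulate_cohort <- function(config = cohort_config(),
                            id_design = identification_design(),
                            disc_design = discrimination_design()) {
  profiles <- generate_cohort(config)
  n <- nrow(profiles)
  id_list <- vector("list", n)
  disc_list <- vector("list", n)
  score_list <- vector("list", n)
  for (i in seq_len(n)) {
    pr <- profiles[i, ]
    s <- child_seed(config$seed, i)
    idt <- simulate_identification(pr, id_design, seed = s)
    dit <- simulate_discrimination(pr, disc_design, config, seed = s + 1L)
    idt$participant_id <- pr$participant_id
    dit$participant_id <- pr$participant_id
    id_list[[i]] <- idt[, c("participant_id", "trial", "vot_ms", "response")]
    disc_list[[i]] <- dit[, c("participant_id", "trial", "vot_a_ms",
                              "vot_b_ms", "response")]
    score_list[[i]] <- simulate_task_scores(pr, config$norms, config,
                                            seed = s + 2L)
  }
  participants <- cbind(
    profiles[, c("participant_id", "group", "dyslexic", "age_months")],
    do.call(rbind, score_list)[, -1L])
  structure(list(profiles = profiles,
                 participants = participants,
                 identification = do.call(rbind, id_list),
                 discrimination = do.call(rbind, disc_list),
                 config = config),
            class = "cohort_data")
}
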