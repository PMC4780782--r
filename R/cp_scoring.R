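#' Tabulate an identification curve
#'
#' Aggregates trial-level identification responses into per-VOT counts and
#' /t/-labeling proportions. Input order is irrelevant; every continuum
#' level must be represented.
#'
#' @param trials data frame with columns `vot_ms` and `response`
#'   (`"d"`/`"t"`).
#' @param continuum the [vot_continuum()] the trials were drawn from.
#' @return A data frame of class `"identification_curve"` with columns
#'   `vot_ms`, `n_t`, `n_total`, `p_t`, ordered by VOT.
#' @export
tabulate_identification <- function(trials, continuum = vot_continuum()) {
  stopifnot(is.data.frame(trials), all(c("vot_ms", "response") %in% names(trials)))
  bad <- setdiff(unique(trials$response), c("d", "t"))
  if (length(bad) > 0L)
    stop("unknown response values: ", paste(bad, collapse = ", "))
  lev <- as.integer(continuum)
  missing_lev <- setdiff(lev, unique(trials$vot_ms))
  if (length(missing_lev) > 0L)
    stop("no trials at VOT level(s): ", paste(missing_lev, collapse = ", "), " ms")
  f <- factor(trials$vot_ms, levels = lev)
  n_total <- as.integer(table(f))
  n_t <- as.integer(table(f[trials$response == "t"]))
  out <- data.frame(vot_ms = lev, n_t = n_t, n_total = n_total,
                    p_t = n_t / n_total)
  structure(out, class = c("identification_curve", "data.frame"))
}

# Firth (Jeffreys-prior penalized) logistic IRLS on binomial counts.
# Returns the coefficient vector of y ~ x or NULL on numerical failure.
firth_logistic <- function(x_vals, y_counts, n_counts, maxit = 100L,
                           tol = 1e-10) {
  X <- cbind(1, x_vals)
  b <- c(0, 0.05)
  for (it in seq_len(maxit)) {
    p <- stats::plogis(drop(X %*% b))
    w <- n_counts * p * (1 - p)
    XWX <- crossprod(X, w * X)
    XWXi <- tryCatch(solve(XWX), error = function(e) NULL)
    if (is.null(XWXi)) return(NULL)
    h <- rowSums((sqrt(w) * X) %*% XWXi * (sqrt(w) * X))
    U <- crossprod(X, y_counts - n_counts * p + h * (0.5 - p))
    db <- drop(XWXi %*% U)
    if (!all(is.finite(db))) return(NULL)
    b <- b + db
    if (max(abs(db)) < tol) return(b)
  }
  b
}

#' Fit the phonemic boundary by penalized logistic maximum likelihood
#'
#' Fits `P(/t/) = logistic((VOT - mu) / s)` to the Bernoulli counts of an
#' identification curve. `mu` is the 50% crossing (the phonemic boundary,
#' ms VOT) and `s` the slope scale (ms; smaller = sharper identification).
#' The likelihood is penalized by the Jeffreys prior (Firth's correction),
#' which removes the small-sample bias of the plain MLE on this sparse
#' six-point grid and keeps the estimate finite for near-step curves,
#' where the unpenalized fit diverges under complete separation. When all
#' responses share one label, or the fit yields a non-positive slope (a
#' reversed or flat labeler), the boundary is non-identifiable:
#' `converged = FALSE` and `mu`/`s` are `NA`.
#'
#' @param curve an [tabulate_identification()] curve.
#' @return A list of class `"boundary_fit"`: `mu_ms`, `s_ms`, `converged`,
#'   `method`.
#' @export
fit_boundary <- function(curve) {
  stopifnot(inherits(curve, "identification_curve"))
  degenerate <- all(curve$n_t == 0L) || all(curve$n_t == curve$n_total)
  res <- list(mu_ms = NA_real_, s_ms = NA_real_, converged = FALSE,
              method = "firth-logistic-mle")
  if (!degenerate) {
    b <- firth_logistic(curve$vot_ms, curve$n_t, curve$n_total)
    if (!is.null(b) && all(is.finite(b)) && b[2] > 0) {
      res$mu_ms <- unname(-b[1] / b[2])
      res$s_ms <- unname(1 / b[2])
      res$converged <- TRUE
    }
  }
  structure(res, class = "boundary_fit")
}

#' Observed hit and false-alarm rates for one VOT pair
#'
#' For the adjacent pair `(i, j)`: the hit rate is the proportion of
#' "different" responses pooled over both presentation orders `(i, j)` and
#' `(j, i)`; the false-alarm rate is the mean of the "different"
#' proportions on the two flanking identical pairs `(i, i)` and `(j, j)`.
#'
#' @param trials discrimination trial table (`vot_a_ms`, `vot_b_ms`,
#'   `response` in `"same"`/`"different"`).
#' @param vot_i,vot_j the two VOT levels of the pair.
#' @return A list `hit_rate`, `fa_rate`, `n_hit_trials`, `n_fa_trials`.
#' @export
observed_pair_rates <- function(trials, vot_i, vot_j) {
  stopifnot(all(c("vot_a_ms", "vot_b_ms", "response") %in% names(trials)))
  sel <- function(a, b) trials$vot_a_ms == a & trials$vot_b_ms == b
  need <- list(c(vot_i, vot_j), c(vot_j, vot_i), c(vot_i, vot_i), c(vot_j, vot_j))
  n <- vapply(need, function(p) sum(sel(p[1], p[2])), 0L)
  if (any(n == 0L)) {
    miss <- vapply(need[n == 0L], function(p) paste0("(", p[1], ",", p[2], ")"), "")
    stop("no trials for pair(s): ", paste(miss, collapse = ", "))
  }
  diff_resp <- trials$response == "different"
  hits <- sum(diff_resp[sel(vot_i, vot_j) | sel(vot_j, vot_i)])
  hit_rate <- hits / (n[1] + n[2])
  fa_rate <- mean(c(mean(diff_resp[sel(vot_i, vot_i)]),
                    mean(diff_resp[sel(vot_j, vot_j)])))
  list(hit_rate = hit_rate, fa_rate = fa_rate,
       n_hit_trials = as.integer(n[1] + n[2]),
       n_fa_trials = as.integer(n[3] + n[4]))
}

#' Signal-detection sensitivity with log-linear correction
#'
#' `d' = z(H*) - z(F*)`, the difference of standard-normal quantiles of
#' the log-linear-corrected hit and false-alarm rates. The correction adds
#' 0.5 to the numerator count and 1 to the denominator count and is
#' applied to every rate (not only at 0 or 1), so observed and predicted
#' scores share one transform and d' is always finite.
#'
#' @param hit_rate,fa_rate proportions in `[0, 1]`.
#' @param n_hit_trials,n_fa_trials trial counts behind the two rates.
#' @return The corrected d' (numeric scalar).
#' @export
dprime <- function(hit_rate, fa_rate, n_hit_trials, n_fa_trials) {
  if (any(c(hit_rate, fa_rate) < 0) || any(c(hit_rate, fa_rate) > 1))
    stop("rates must be in [0, 1]")
  if (n_hit_trials < 1L || n_fa_trials < 1L) stop("trial counts must be >= 1")
  h <- (hit_rate * n_hit_trials + 0.5) / (n_hit_trials + 1)
  f <- (fa_rate * n_fa_trials + 0.5) / (n_fa_trials + 1)
  qnorm(h) - qnorm(f)
}

#' Predicted probability of different covert labels
#'
#' Under the covert-labeling model of AX discrimination, two stimuli are
#' judged "different" when they receive different covert phoneme labels:
#' `p_i (1 - p_j) + p_j (1 - p_i)`, with `p` the /t/-labeling
#' probabilities. Symmetric in its arguments and bounded by `[0, 1]`.
#'
#' @param p_i,p_j labeling probabilities in `[0, 1]` (vectorized).
#' @return Probability of different labels.
#' @export
predicted_different_prob <- function(p_i, p_j) {
  if (any(p_i < 0 | p_i > 1 | p_j < 0 | p_j > 1))
    stop("labeling probabilities must be in [0, 1]")
  p_i * (1 - p_j) + p_j * (1 - p_i)
}

# The five adjacent pairs of a continuum with their centers.
adjacent_pairs <- function(continuum = vot_continuum()) {
  k <- as.integer(continuum)
  data.frame(vot_a = k[-length(k)], vot_b = k[-1],
             center_ms = (k[-length(k)] + k[-1]) / 2)
}

#' Extract the discrimination peak
#'
#' The peak is the pair with the largest d'. Ties are broken toward the
#' smallest absolute center, then toward the negative center.
#'
#' @param center_ms pair centers (ms).
#' @param dprimes d' values, same length.
#' @return A list `peak_center_ms`, `peak_amplitude`.
#' @export
find_peak <- function(center_ms, dprimes) {
  stopifnot(length(center_ms) == length(dprimes), length(dprimes) >= 1L)
  ord <- order(-dprimes, abs(center_ms), center_ms)
  list(peak_center_ms = center_ms[ord[1]], peak_amplitude = dprimes[ord[1]])
}

profile_frame <- function(pairs, hit, fa, dp, kind) {
  scores <- data.frame(vot_a = pairs$vot_a, vot_b = pairs$vot_b,
                       center_ms = pairs$center_ms,
                       hit_rate = hit, fa_rate = fa, dprime = dp,
                       kind = kind)
  pk <- find_peak(scores$center_ms, scores$dprime)
  structure(list(scores = scores, peak_center_ms = pk$peak_center_ms,
                 peak_amplitude = pk$peak_amplitude, kind = kind),
            class = "discrimination_profile")
}

#' Predicted discrimination profile from an identification curve
#'
#' Converts labeling proportions into the discrimination performance an
#' ideal covert labeler would show. For each adjacent pair, the predicted
#' hit rate is [predicted_different_prob()] of the two levels' `p_t`; the
#' predicted false-alarm rate is the mean of the two identical-pair
#' different-label probabilities `2 p (1 - p)`. Both are converted to d'
#' with the same log-linear correction as observed scores, using the
#' identification design's trial counts as pseudo-counts.
#'
#' @param curve an [tabulate_identification()] curve.
#' @param continuum the continuum (defaults to the curve's levels).
#' @return A `"discrimination_profile"` (`kind = "predicted"`) holding the
#'   five pair scores and the extracted peak.
#' @export
predicted_profile <- function(curve, continuum = vot_continuum(curve$vot_ms)) {
  stopifnot(inherits(curve, "identification_curve"))
  pairs <- adjacent_pairs(continuum)
  ia <- match(pairs$vot_a, curve$vot_ms)
  ib <- match(pairs$vot_b, curve$vot_ms)
  p_a <- curve$p_t[ia]; p_b <- curve$p_t[ib]
  hit <- predicted_different_prob(p_a, p_b)
  fa <- (2 * p_a * (1 - p_a) + 2 * p_b * (1 - p_b)) / 2
  n_pseudo <- curve$n_total[ia] + curve$n_total[ib]
  dp <- mapply(dprime, hit, fa, n_pseudo, n_pseudo)
  profile_frame(pairs, hit, fa, dp, "predicted")
}

#' Observed discrimination profile from trial data
#'
#' Scores a complete discrimination block into five pair scores (centers
#' -60, -30, 0, +30, +60 ms on the default continuum) with corrected d'
#' and the extracted peak.
#'
#' @param trials discrimination trial table for one participant.
#' @param continuum the [vot_continuum()].
#' @return A `"discrimination_profile"` (`kind = "observed"`).
#' @export
observed_profile <- function(trials, continuum = vot_continuum()) {
  pairs <- adjacent_pairs(continuum)
  rates <- lapply(seq_len(nrow(pairs)), function(i)
    observed_pair_rates(trials, pairs$vot_a[i], pairs$vot_b[i]))
  hit <- vapply(rates, `[[`, 0, "hit_rate")
  fa <- vapply(rates, `[[`, 0, "fa_rate")
  dp <- vapply(rates, function(r)
    dprime(r$hit_rate, r$fa_rate, r$n_hit_trials, r$n_fa_trials), 0)
  profile_frame(pairs, hit, fa, dp, "observed")
}

#' Location, spread and skewness of a boundary distribution
#'
#' Mean, sample SD and bias-adjusted Fisher-Pearson skewness (G1) of a
#' group's fitted phonemic boundaries. Missing values (non-converged fits)
#' are dropped; at least three values must remain.
#'
#' @param boundaries_ms numeric vector of boundary locations (ms).
#' @return A list `mean_ms`, `sd_ms`, `skewness`, `n`.
#' @export
boundary_distribution_stats <- function(boundaries_ms) {
  x <- boundaries_ms[!is.na(boundaries_ms)]
  n <- length(x)
  if (n < 3L) stop("need at least 3 non-missing boundaries, got ", n)
  m2 <- mean((x - mean(x))^2)
  m3 <- mean((x - mean(x))^3)
  g1 <- m3 / m2^1.5
  list(mean_ms = mean(x), sd_ms = sd(x),
       skewness = g1 * sqrt(n * (n - 1)) / (n - 2), n = n)
}

#' Per-participant derived CP variables
#'
#' Applies the whole CP scoring chain to a cohort's trial tables: boundary
#' fit, observed and predicted d' at each pair center, and the peak
#' center/amplitude of both profiles.
#'
#' @param identification trial table with `participant_id`, `vot_ms`,
#'   `response`.
#' @param discrimination trial table with `participant_id`, `vot_a_ms`,
#'   `vot_b_ms`, `response`.
#' @param continuum the [vot_continuum()].
#' @return A data frame, one row per participant: `boundary_mu_ms`,
#'   `boundary_s_ms`, `boundary_converged`, `obs_d_*` and `pred_d_*`
#'   columns per center, and observed/predicted peak center and amplitude.
#' @export
score_participants <- function(identification, discrimination,
                               continuum = vot_continuum()) {
  ids_i <- unique(identification$participant_id)
  ids_d <- unique(discrimination$participant_id)
  orphan <- union(setdiff(ids_i, ids_d), setdiff(ids_d, ids_i))
  if (length(orphan) > 0L)
    stop("participants missing one of the two trial tables: ",
         paste(orphan, collapse = ", "))
  centers <- adjacent_pairs(continuum)$center_ms
  lab <- function(x) gsub("-", "m", as.character(x))
  rows <- lapply(ids_i, function(id) {
    curve <- tabulate_identification(
      identification[identification$participant_id == id, ], continuum)
    bf <- fit_boundary(curve)
    obs <- observed_profile(
      discrimination[discrimination$participant_id == id, ], continuum)
    pred <- predicted_profile(curve, continuum)
    row <- data.frame(participant_id = id,
                      boundary_mu_ms = bf$mu_ms, boundary_s_ms = bf$s_ms,
                      boundary_converged = bf$converged)
    row[paste0("obs_d_", lab(centers))] <- as.list(obs$scores$dprime)
    row[paste0("pred_d_", lab(centers))] <- as.list(pred$scores$dprime)
    row$obs_peak_center <- obs$peak_center_ms
    row$obs_peak_amplitude <- obs$peak_amplitude
    row$pred_peak_center <- pred$peak_center_ms
    row$pred_peak_amplitude <- pred$peak_amplitude
    row
  })
  do.call(rbind, rows)
}
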