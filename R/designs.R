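#' The VOT continuum
#'
#' Construct the voice onset time (VOT) continuum underlying the /d/-/t/
#' identification and discrimination tasks. The default is the six-step
#' continuum from -75 to +75 ms in 30 ms steps.
#'
#' @param levels_ms integer VOT values in milliseconds, strictly increasing,
#'   even count (so that adjacent-pair centers fall midway between steps).
#' @return An integer vector of class `"vot_continuum"`.
#' @examples
#' vot_continuum()
#' @export
vot_continuum <- function(levels_ms = c(-75L, -45L, -15L, 15L, 45L, 75L)) {
  levels_ms <- as.integer(levels_ms)
  if (length(levels_ms) < 2L || length(levels_ms) %% 2L != 0L)
    stop("continuum must have an even number (>= 2) of levels")
  if (any(diff(levels_ms) <= 0L))
    stop("continuum levels must be strictly increasing")
  structure(levels_ms, class = "vot_continuum")
}

#' Balanced identification design
#'
#' One block of identification trials: every continuum level repeated
#' `reps` times, in a seeded random order (Fisher-Yates permutation via R's
#' `sample`). The default reproduces the standard 60-trial block
#' (10 trials at each of 6 VOT values).
#'
#' @param continuum a [vot_continuum()].
#' @param reps trials per level (>= 1).
#' @param seed integer seed controlling trial order only.
#' @return A data frame of class `"identification_design"` with columns
#'   `trial` and `vot_ms`, plus attribute `reps`.
#' @export
identification_design <- function(continuum = vot_continuum(), reps = 10L,
                                  seed = 0L) {
  stopifnot(inherits(continuum, "vot_continuum"))
  reps <- as.integer(reps)
  if (is.na(reps) || reps < 1L) stop("reps must be >= 1")
  vots <- rep(as.integer(continuum), reps)
  ord <- with_seed(seed, sample.int(length(vots)))
  out <- data.frame(trial = seq_along(vots), vot_ms = vots[ord])
  structure(out, class = c("identification_design", "data.frame"),
            reps = reps, continuum = continuum)
}

# All pairs of the AX discrimination block: every identical pair (k, k)
# and both orders of every one-step pair on the grid.
discrimination_pairs <- function(continuum = vot_continuum()) {
  k <- as.integer(continuum)
  same <- data.frame(vot_a = k, vot_b = k)
  adj <- data.frame(vot_a = k[-length(k)], vot_b = k[-1])
  diff <- rbind(adj, data.frame(vot_a = adj$vot_b, vot_b = adj$vot_a))
  out <- rbind(same, diff)
  out$is_identical <- out$vot_a == out$vot_b
  out
}

#' Balanced AX discrimination design
#'
#' One block of same-different (AX) trials: every identical pair `(k, k)`
#' and both presentation orders of every adjacent pair of the continuum,
#' each repeated `reps` times, in a seeded random order. The default
#' reproduces the standard 80-trial block (6 identical + 10 different pairs,
#' 5 repetitions each).
#'
#' @inheritParams identification_design
#' @param reps repetitions per pair (>= 1).
#' @return A data frame of class `"discrimination_design"` with columns
#'   `trial`, `vot_a_ms`, `vot_b_ms`, `is_identical`.
#' @export
discrimination_design <- function(continuum = vot_continuum(), reps = 5L,
                                  seed = 0L) {
  stopifnot(inherits(continuum, "vot_continuum"))
  reps <- as.integer(reps)
  if (is.na(reps) || reps < 1L) stop("reps must be >= 1")
  pairs <- discrimination_pairs(continuum)
  idx <- rep(seq_len(nrow(pairs)), each = reps)
  ord <- with_seed(seed, sample.int(length(idx)))
  p <- pairs[idx[ord], , drop = FALSE]
  out <- data.frame(trial = seq_along(ord),
                    vot_a_ms = p$vot_a, vot_b_ms = p$vot_b,
                    is_identical = p$is_identical)
  structure(out, class = c("discrimination_design", "data.frame"),
            reps = reps, continuum = continuum)
}

#' Single-letter identification control design
#'
#' Each of the ten report-task consonants is presented once at each of the
#' five masked presentation durations (50 trials), in seeded random order.
#' This task controls that poor letter report reflects multi-element
#' processing rather than single-letter identification.
#'
#' @param letters the letter set (default the ten consonants of the report
#'   tasks).
#' @param durations_ms presentation durations in milliseconds.
#' @param seed integer seed controlling trial order only.
#' @return A data frame of class `"single_letter_design"` with columns
#'   `trial`, `letter`, `duration_ms`.
#' @export
single_letter_design <- function(letters = report_alphabet(),
                                 durations_ms = c(33L, 50L, 67L, 84L, 101L),
                                 seed = 0L) {
  if (anyDuplicated(letters)) stop("letters must be distinct")
  grid <- expand.grid(letter = letters, duration_ms = as.integer(durations_ms),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ord <- with_seed(seed, sample.int(nrow(grid)))
  out <- data.frame(trial = seq_len(nrow(grid)),
                    letter = grid$letter[ord],
                    duration_ms = grid$duration_ms[ord])
  structure(out, class = c("single_letter_design", "data.frame"))
}
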