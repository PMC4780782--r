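#' The letter-report alphabet
#'
#' The ten consonants used in the global/partial report and single-letter
#' tasks.
#' @return Character vector of length 10.
#' @export
report_alphabet <- function() c("B", "P", "T", "F", "L", "M", "D", "S", "R", "H")

#' Default forbidden adjacent letter pairs
#'
#' Bigrams excluded from adjacent positions of report strings: French
#' graphemes (PH, TH) and frequent French bigrams (TR, PL, BR), plus their
#' reverses. Full lexicon screening against real-word skeletons would need
#' a French word list and is out of scope; the blocklist is configurable.
#' @return Character vector of two-letter strings.
#' @export
default_forbidden_bigrams <- function() {
  fwd <- c("PH", "TH", "TR", "PL", "BR")
  rev <- vapply(strsplit(fwd, ""), function(x) paste0(x[2], x[1]), "")
  unique(c(fwd, rev))
}

# Sample one string of `len` letters respecting remaining per-position
# quotas, no within-string repeats and the forbidden-bigram blocklist.
# Returns a character vector or NULL on dead end.
sample_string <- function(quota, forbidden, len) {
  letters_all <- rownames(quota)
  s <- character(len)
  for (pos in seq_len(len)) {
    cand <- letters_all[quota[, pos] > 0L]
    cand <- setdiff(cand, s[seq_len(pos - 1L)])
    if (length(cand) == 0L) return(NULL)
    if (pos > 1L)
      cand <- cand[!paste0(s[pos - 1L], cand) %in% forbidden]
    if (length(cand) == 0L) return(NULL)
    w <- quota[cand, pos]
    s[pos] <- if (length(cand) == 1L) cand else
      sample(cand, 1L, prob = w^2)  # favour tight quotas to avoid dead ends
  }
  s
}

# Kuhn's augmenting-path bipartite matching: assign each (letter, position)
# cue combination to a distinct trial displaying that letter at that
# position. adj is a list over combos of candidate trial indices.
match_cues <- function(adj, n_trials) {
  match_of_trial <- integer(n_trials)  # 0 = free
  for (ci in seq_along(adj)) {
    seen <- rep(FALSE, n_trials)
    augment <- function(c2) {
      for (t in adj[[c2]]) {
        if (seen[t]) next
        seen[t] <<- TRUE
        if (match_of_trial[t] == 0L || augment(match_of_trial[t])) {
          match_of_trial[t] <<- c2
          return(TRUE)
        }
      }
      FALSE
    }
    if (!augment(ci)) return(NULL)
  }
  # invert: combo -> trial
  out <- integer(length(adj))
  out[match_of_trial[match_of_trial > 0L]] <- which(match_of_trial > 0L)
  out
}

#' Letter-report stimulus designs (global and partial report)
#'
#' Generate the five-letter consonant strings of the visual attention span
#' report tasks by seeded randomized construction (column-balanced quota
#' sampling with restart on dead ends):
#' \itemize{
#'   \item `mode = "global"`: 20 strings; each letter used 10 times in
#'     total and exactly twice in each of the 5 positions;
#'   \item `mode = "partial"`: 50 strings; each letter used 25 times, 5 per
#'     position, and additionally cued as report target exactly once in
#'     each position (50 cues covering every letter-position combination).
#' }
#' No string repeats a letter and no two adjacent letters form a forbidden
#' bigram. Cues are assigned by bipartite matching so that each trial
#' carries exactly one cue.
#'
#' @param mode `"global"` or `"partial"`.
#' @param alphabet 10 distinct letters.
#' @param forbidden_bigrams character vector of excluded ordered adjacent
#'   pairs (two-letter strings).
#' @param seed integer seed.
#' @param max_attempts restarts allowed before the constraint set is
#'   declared unsatisfiable.
#' @return A list of class `"letter_report_design"` with elements
#'   `mode`, `strings` (character vector), `letters` (trials x 5 character
#'   matrix), and for partial report `cue_position` (integer per trial) and
#'   `cue_letter`.
#' @seealso [validate_letter_report()] for the independent post-hoc check.
#' @export
letter_report_design <- function(mode = c("global", "partial"),
                                 alphabet = report_alphabet(),
                                 forbidden_bigrams = default_forbidden_bigrams(),
                                 seed = 0L, max_attempts = 100L) {
  mode <- match.arg(mode)
  alphabet <- as.character(alphabet)
  if (length(alphabet) != 10L || anyDuplicated(alphabet))
    stop("alphabet must contain 10 distinct letters")
  if (max_attempts < 1L) stop("max_attempts must be >= 1")
  n_pos <- 5L
  per_pos <- if (mode == "global") 2L else 5L
  n_trials <- if (mode == "global") 20L else 50L

  with_seed(seed, {
    mat <- NULL
    for (attempt in seq_len(max_attempts)) {
      quota <- matrix(per_pos, nrow = length(alphabet), ncol = n_pos,
                      dimnames = list(alphabet, NULL))
      rows <- vector("list", n_trials)
      ok <- TRUE
      for (t in seq_len(n_trials)) {
        s <- NULL
        for (retry in 1:50) {
          s <- sample_string(quota, forbidden_bigrams, n_pos)
          if (!is.null(s)) break
        }
        if (is.null(s)) { ok <- FALSE; break }
        rows[[t]] <- s
        ij <- cbind(match(s, alphabet), seq_len(n_pos))
        quota[ij] <- quota[ij] - 1L
      }
      if (ok) { mat <- do.call(rbind, rows); break }
    }
    if (is.null(mat))
      stop("could not satisfy letter-report constraints in ", max_attempts,
           " attempts; the forbidden-bigram list may be over-restrictive")

    out <- list(mode = mode, strings = apply(mat, 1L, paste0, collapse = ""),
                letters = mat)
    if (mode == "partial") {
      combos <- expand.grid(letter = alphabet, pos = seq_len(n_pos),
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      combos <- combos[sample.int(nrow(combos)), , drop = FALSE]
      adj <- lapply(seq_len(nrow(combos)), function(i) {
        sample(which(mat[, combos$pos[i]] == combos$letter[i]))
      })
      m <- match_cues(adj, n_trials)
      if (is.null(m))
        stop("internal error: cue matching failed on a balanced design")
      cue_pos <- integer(n_trials)
      cue_pos[m] <- combos$pos
      out$cue_position <- cue_pos
      out$cue_letter <- mat[cbind(seq_len(n_trials), cue_pos)]
    }
    structure(out, class = "letter_report_design")
  })
}

#' Independent check of letter-report invariants
#'
#' Recounts the balance and adjacency constraints of a
#' [letter_report_design()] from the realized strings, without reusing the
#' generator's bookkeeping: total and per-position letter counts, no
#' repeated letter within a string, no forbidden adjacent bigram and, for
#' partial report, one cue per trial covering each letter-position
#' combination exactly once.
#'
#' @param design a `"letter_report_design"`.
#' @param alphabet,forbidden_bigrams the constraint set to check against.
#' @return Invisibly `TRUE`; stops with a message on the first violated
#'   constraint.
#' @export
validate_letter_report <- function(design, alphabet = report_alphabet(),
                                   forbidden_bigrams = default_forbidden_bigrams()) {
  stopifnot(inherits(design, "letter_report_design"))
  mat <- design$letters
  per_pos <- if (design$mode == "global") 2L else 5L
  for (p in seq_len(ncol(mat))) {
    cnt <- table(factor(mat[, p], levels = alphabet))
    if (any(cnt != per_pos))
      stop("position ", p, ": letter counts are not all ", per_pos)
  }
  tot <- table(factor(as.vector(mat), levels = alphabet))
  if (any(tot != per_pos * ncol(mat)))
    stop("total letter counts are not all ", per_pos * ncol(mat))
  if (any(apply(mat, 1L, anyDuplicated) > 0L))
    stop("a string repeats a letter")
  big <- paste0(mat[, -ncol(mat)], mat[, -1L])
  if (any(big %in% forbidden_bigrams))
    stop("a string contains a forbidden bigram")
  if (design$mode == "partial") {
    if (length(design$cue_position) != nrow(mat))
      stop("cue count differs from trial count")
    cued <- paste0(design$cue_letter, design$cue_position)
    want <- as.vector(outer(alphabet, seq_len(ncol(mat)), paste0))
    if (!setequal(cued, want) || anyDuplicated(cued))
      stop("cues do not cover each letter-position combination exactly once")
  }
  invisible(TRUE)
}

#' @export
as.data.frame.letter_report_design <- function(x, ...) {
  data.frame(trial = seq_along(x$strings), string = x$strings,
             cue_position = if (x$mode == "partial") x$cue_position else NA_integer_)
}
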