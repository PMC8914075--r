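# Simulated verbal repetition responses: per-trial correctness follows a
# logistic link from clear<->degraded envelope similarity (match trials)
# or a floor probability (mismatch trials), with a subject random effect.

PHONEME_CONSONANTS <- c("p", "t", "k", "b", "d", "g", "m", "n", "l", "s", "f", "r")
PHONEME_VOWELS <- c("a", "e", "i", "o", "u")

# A random 2-syllable CV phoneme string, e.g. "t a l o".
random_phoneme_word <- function(n_syllables = 2L) {
  paste(unlist(lapply(seq_len(n_syllables), function(i)
    c(sample(PHONEME_CONSONANTS, 1L), sample(PHONEME_VOWELS, 1L)))),
    collapse = " ")
}

# Substitute `k` phonemes of a word for different alphabet members.
mutate_phonemes <- function(word, k) {
  ph <- strsplit(word, " ", fixed = TRUE)[[1L]]
  pos <- sample(seq_along(ph), min(k, length(ph)))
  for (p in pos) {
    pool <- if (ph[p] %in% PHONEME_VOWELS) PHONEME_VOWELS else PHONEME_CONSONANTS
    ph[p] <- sample(setdiff(pool, ph[p]), 1L)
  }
  paste(ph, collapse = " ")
}

#' Simulate repetition responses for a schedule
#'
#' Builds a trial table for `n_subjects` participants and realises verbal
#' responses. On match (and catch-match) trials the probability of a fully
#' correct repetition is `plogis(intercept + slope * similarity + u_s)`
#' with a per-subject normal effect `u_s`; on mismatch trials it is the
#' floor `plogis(qlogis(mismatch_floor) + u_s)`. Incorrect repetitions are
#' realised as one phoneme substitution (score 0.5) with probability
#' `p_half`, otherwise two or more substitutions (score 0); on mismatch
#' trials a fraction `cw_rep_rate` of fully incorrect responses repeats the
#' clear pseudoword instead. On mismatch trials near-misses are rare
#' (`p_half_mismatch`): an unintelligible degraded pseudoword is usually
#' reported wholly wrong. Defaults are calibrated to the study conditions
#' the generator emulates (scored condition means near 68% and 3%, a
#' 13.6% clear-word repetition rate among incorrect mismatch responses).
#'
#' @param schedule An [generate_schedule()] result (its per-trial table
#'   defines conditions); pseudowords are drawn per trial.
#' @param n_subjects Number of simulated participants.
#' @param similarity Per-trial envelope similarity values in roughly
#'   `[0.18, 0.53]`; default drawn uniformly over that range (one value per
#'   trial, shared across subjects, as each pseudoword has one degraded
#'   version).
#' @param slope,intercept Psychometric link coefficients on the logit scale.
#' @param mismatch_floor Correct-repetition probability floor on mismatch
#'   trials.
#' @param subject_sd SD of the subject random effect (logit scale).
#' @param p_half Probability that an incorrect match-trial response has
#'   exactly one wrong phoneme.
#' @param p_half_mismatch As `p_half`, for mismatch trials.
#' @param cw_rep_rate Probability that a fully incorrect mismatch response
#'   repeats the clear pseudoword.
#' @param seed Integer seed.
#' @return A scored trial data frame: `subject`, `trial`, `condition`,
#'   `similarity`, `reference`, `clear_word`, `response`, `score`,
#'   `cw_repeated`.
#' @export
simulate_responses <- function(schedule, n_subjects = 20L, similarity = NULL,
                               slope = 8, intercept = -2.4,
                               mismatch_floor = 0.02, subject_sd = 0.5,
                               p_half = 0.5, p_half_mismatch = 0.03,
                               cw_rep_rate = 0.136, seed = 1L) {
  trials <- attr(schedule, "trials")
  if (is.null(trials)) stop("schedule carries no trial table")
  set.seed(as.integer(seed))
  n_trials <- nrow(trials)
  if (is.null(similarity)) similarity <- stats::runif(n_trials, 0.18, 0.53)
  if (length(similarity) != n_trials)
    stop("need one similarity value per trial")
  words <- vapply(seq_len(n_trials), function(i) random_phoneme_word(), character(1))
  clear <- words
  mis <- grepl("mismatch", trials$condition)
  clear[mis] <- vapply(which(mis), function(i) {
    w <- random_phoneme_word()
    while (w == words[i]) w <- random_phoneme_word()
    w
  }, character(1))
  u <- stats::rnorm(n_subjects, 0, subject_sd)

  out <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    eta <- ifelse(mis, stats::qlogis(mismatch_floor) + u[s],
                  intercept + slope * similarity + u[s])
    p_correct <- stats::plogis(eta)
    correct <- stats::runif(n_trials) < p_correct
    resp <- character(n_trials)
    cwrep <- logical(n_trials)
    for (i in seq_len(n_trials)) {
      p_half_i <- if (mis[i]) p_half_mismatch else p_half
      if (correct[i]) {
        resp[i] <- words[i]
      } else if (stats::runif(1) < p_half_i) {
        resp[i] <- mutate_phonemes(words[i], 1L)
      } else if (mis[i] && stats::runif(1) < cw_rep_rate) {
        resp[i] <- clear[i]
        cwrep[i] <- TRUE
      } else {
        resp[i] <- mutate_phonemes(words[i], 2L)
      }
    }
    out[[s]] <- data.frame(subject = s, trial = trials$trial,
                           condition = trials$condition,
                           similarity = similarity,
                           reference = words, clear_word = clear,
                           response = resp, stringsAsFactors = FALSE)
  }
  score_trials(do.call(rbind, out))
}
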