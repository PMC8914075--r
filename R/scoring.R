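# Whole-pseudoword repetition scoring: 1 for a flawless repetition, 0.5 for
# exactly one wrong phoneme, 0 otherwise (including missing responses).

# Levenshtein distance between two phoneme label vectors, unit costs.
phoneme_edit_distance <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  n <- length(a); m <- length(b)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- numeric(m + 1L)
    cur[1L] <- i
    for (j in seq_len(m)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1,            # deletion
                         cur[j] + 1,                  # insertion
                         prev[j] + (a[i] != b[j]))    # substitution
    }
    prev <- cur
  }
  prev[m + 1L]
}

#' Score a verbal pseudoword repetition
#'
#' Three-level whole-pseudoword grading: 1 if the response reproduces the
#' reference without mistake, 0.5 if exactly one phoneme is incorrectly
#' reported, 0 if more than one phoneme is wrong or the response is
#' missing. The number of incorrect phonemes is the minimum edit distance
#' (substitutions, insertions, deletions at unit cost) between reference
#' and response; `mode = "positional"` instead counts positionwise
#' mismatches plus the length difference.
#'
#' @param reference Character vector of reference phoneme labels (non-empty).
#' @param response Character vector of response phonemes; `NULL`,
#'   zero-length or `NA` counts as a missing response.
#' @param mode `"edit"` (default) or `"positional"` error counting.
#' @return A score in `{0, 0.5, 1}`.
#' @export
score_response <- function(reference, response, mode = c("edit", "positional")) {
  mode <- match.arg(mode)
  reference <- as.character(reference)
  if (length(reference) == 0L) stop("reference pseudoword must be non-empty")
  if (is.null(response) || length(response) == 0L || all(is.na(response)))
    return(0)
  response <- as.character(response)
  errors <- if (mode == "edit") {
    phoneme_edit_distance(reference, response)
  } else {
    k <- min(length(reference), length(response))
    sum(reference[seq_len(k)] != response[seq_len(k)]) +
      abs(length(reference) - length(response))
  }
  if (errors == 0L) 1 else if (errors == 1L) 0.5 else 0
}

#' Score a table of trials
#'
#' @param trials Data frame with at least `reference` and `response` columns
#'   holding phoneme sequences as strings with phonemes separated by `sep`
#'   (empty string = missing response).
#' @param sep Phoneme separator within the sequence strings.
#' @param mode Passed to [score_response()].
#' @return `trials` with a numeric `score` column (and `cw_repeated` set
#'   from column `clear_word` when present: response identical to the clear
#'   pseudoword).
#' @export
score_trials <- function(trials, sep = " ", mode = "edit") {
  stopifnot(is.data.frame(trials), all(c("reference", "response") %in% names(trials)))
  split_seq <- function(s) {
    if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, sep, fixed = TRUE)[[1L]]
  }
  trials$score <- vapply(seq_len(nrow(trials)), function(i) {
    score_response(split_seq(trials$reference[i]), split_seq(trials$response[i]),
                   mode = mode)
  }, numeric(1))
  if ("clear_word" %in% names(trials)) {
    trials$cw_repeated <- !is.na(trials$response) & nzchar(trials$response) &
      trials$response == trials$clear_word
  }
  trials
}

#' Aggregate scores per subject and condition
#'
#' @param trials Scored trial data frame with columns `subject`,
#'   `condition` and `score`.
#' @return A list with `per_subject`: data frame of `subject`, `condition`,
#'   `percent` (mean score x 100; `NA` for empty cells), `n_trials`; and
#'   `group`: per-condition mean and SD of the subject percentages.
#' @export
aggregate_scores <- function(trials) {
  stopifnot(all(c("subject", "condition", "score") %in% names(trials)))
  if (anyNA(trials$score)) stop("all trials must be scored before aggregation")
  subjects <- unique(trials$subject)
  conditions <- unique(trials$condition)
  per <- expand.grid(subject = subjects, condition = conditions,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  per$percent <- NA_real_
  per$n_trials <- 0L
  for (i in seq_len(nrow(per))) {
    sel <- trials$subject == per$subject[i] & trials$condition == per$condition[i]
    per$n_trials[i] <- sum(sel)
    if (any(sel)) per$percent[i] <- 100 * mean(trials$score[sel])
  }
  grp <- do.call(rbind, lapply(conditions, function(cc) {
    v <- per$percent[per$condition == cc & !is.na(per$percent)]
    data.frame(condition = cc, mean = mean(v), sd = stats::sd(v),
               n_subjects = length(v), stringsAsFactors = FALSE)
  }))
  list(per_subject = per, group = grp)
}

#' Paired t-test across subjects
#'
#' Compares two within-subject measurements (e.g. match vs mismatch
#' repetition percentage), `t = mean(d) / (sd(d) / sqrt(n))` on `n - 1`
#' degrees of freedom, two-sided.
#'
#' @param x,y Paired per-subject values of equal length `n >= 2`.
#' @return A [stat_result()]; zero-variance differences yield an infinite
#'   statistic flagged in `effect$zero_variance`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  n <- length(x)
  if (n < 2L) stop("need at least 2 pairs")
  d <- x - y
  if (stats::sd(d) == 0) {
    stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(stat_result(statistic = stat, df = n - 1L,
                       p = if (mean(d) == 0) 1 else 0,
                       effect = list(mean_diff = mean(d), zero_variance = TRUE,
                                     mean_x = mean(x), mean_y = mean(y)),
                       method = "paired t-test"))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  stat_result(statistic = unname(tt$statistic), df = unname(tt$parameter),
              p = tt$p.value,
              effect = list(mean_x = mean(x), sd_x = stats::sd(x),
                            mean_y = mean(y), sd_y = stats::sd(y),
                            mean_diff = mean(d)),
              method = "paired t-test")
}

#' Clear-pseudoword repetition rate among incorrect mismatch trials
#'
#' Share of incorrect (score 0) mismatch-trial responses that repeat the
#' clear pseudoword instead of the degraded one - an index of task
#' adherence.
#'
#' @param trials Scored trial data frame with `condition`, `score` and
#'   logical `cw_repeated` columns.
#' @return Percentage (one decimal); `NA` when there are no incorrect
#'   mismatch trials.
#' @export
cw_repetition_rate <- function(trials) {
  stopifnot(all(c("condition", "score", "cw_repeated") %in% names(trials)))
  sel <- trials$condition %in% c("mismatch", "catch_mismatch") & trials$score == 0
  if (!any(sel)) return(NA_real_)
  round(100 * mean(trials$cw_repeated[sel]), 1)
}
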