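#' Draw jittered intervals from a truncated gamma law
#'
#' ISI/ITI jitter is drawn from a gamma density truncated by rejection to
#' `[min_s, max_s]` seconds, which spreads event spacing to sample the BOLD
#' response efficiently.
#'
#' @param n Number of draws.
#' @param shape,scale Gamma parameters (defaults 2 and 2.5, placing most
#'   mass inside the truncation window).
#' @param min_s,max_s Truncation bounds in seconds (defaults 3 and 16).
#' @return Numeric vector of `n` intervals, all within `[min_s, max_s]`.
#' @export
draw_jitter <- function(n, shape = 2, scale = 2.5, min_s = 3, max_s = 16) {
  stopifnot(n >= 0, shape > 0, scale > 0, min_s < max_s)
  out <- numeric(0)
  while (length(out) < n) {
    d <- stats::rgamma(max(2L * (n - length(out)), 16L), shape = shape, scale = scale)
    out <- c(out, d[d >= min_s & d <= max_s])
  }
  out[seq_len(n)]
}

# Mean of the truncated gamma law by numerical integration; used as an
# oracle for the rejection sampler.
truncated_gamma_mean <- function(shape = 2, scale = 2.5, min_s = 3, max_s = 16) {
  z <- stats::pgamma(max_s, shape, scale = scale) -
       stats::pgamma(min_s, shape, scale = scale)
  stats::integrate(function(x) x * stats::dgamma(x, shape, scale = scale) / z,
                   min_s, max_s)$value
}

#' Generate a trial schedule for the priming paradigm
#'
#' Each trial presents a degraded pseudoword (DW1), a clear pseudoword
#' (CW), and - except on catch trials - the same degraded pseudoword again
#' (DW2), followed by a response cue and the verbal response. The clear
#' pseudoword matches the degraded ones on match trials. All ISIs and the
#' ITI are drawn from the truncated gamma law of [draw_jitter()]. Trials
#' are presented in a seeded pseudorandom order; catch trials are split
#' evenly between match and mismatch forms. Catch-trial DW1/CW onsets fold
#' into the corresponding condition regressors (there is no DW2 onset).
#'
#' @param n_match,n_mismatch,n_catch Trial counts (defaults 61, 61, 12).
#' @param stim_duration Pseudoword duration in seconds.
#' @param response_duration Modeled duration of the verbal response (s).
#' @param tr Scan repetition time in seconds (default 2).
#' @param gamma_shape,gamma_scale,min_s,max_s Jitter law, see [draw_jitter()].
#' @param lead_in Silent lead-in before the first trial (s), covering dummy
#'   scans.
#' @param seed Integer seed (ordering and jitter).
#' @return An `event_schedule`: data frame of events with columns `onset`,
#'   `duration`, `trial_type` (one of the 8 regressor labels
#'   `dw1/cw/dw2/resp x match/mismatch`), `trial`, `condition`; attributes
#'   `trials` (per-trial onset table incl. cue), `tr`, `total_duration`,
#'   `n_scans` and `intervals` (all jitter draws).
#' @export
generate_schedule <- function(n_match = 61L, n_mismatch = 61L, n_catch = 12L,
                              stim_duration = 0.8, response_duration = 1.0,
                              tr = 2, gamma_shape = 2, gamma_scale = 2.5,
                              min_s = 3, max_s = 16, lead_in = 10, seed = 1L) {
  stopifnot(n_match >= 0, n_mismatch >= 0, n_catch >= 0, tr > 0)
  set.seed(as.integer(seed))
  cond <- c(rep("match", n_match), rep("mismatch", n_mismatch),
            rep("catch_match", ceiling(n_catch / 2)),
            rep("catch_mismatch", floor(n_catch / 2)))
  cond <- if (length(cond)) sample(cond) else character(0)
  n_trials <- length(cond)

  ev <- list(); tri <- list(); all_intervals <- numeric(0)
  t <- lead_in
  for (i in seq_len(n_trials)) {
    is_catch <- grepl("^catch", cond[i])
    base <- if (grepl("match$", cond[i]) && !grepl("mismatch$", cond[i]))
      "match" else "mismatch"
    n_iv <- if (is_catch) 3L else 4L  # ISIs + ITI
    iv <- draw_jitter(n_iv, gamma_shape, gamma_scale, min_s, max_s)
    all_intervals <- c(all_intervals, iv)
    dw1 <- t; t <- t + stim_duration + iv[1]
    cw <- t; t <- t + stim_duration + iv[2]
    if (!is_catch) { dw2 <- t; t <- t + stim_duration + iv[3] } else dw2 <- NA_real_
    cue <- t
    resp <- cue
    t <- t + response_duration + iv[n_iv]
    tri[[i]] <- data.frame(trial = i, condition = cond[i], dw1 = dw1, cw = cw,
                           dw2 = dw2, cue = cue, response = resp,
                           stringsAsFactors = FALSE)
    types <- c(paste0("dw1_", base), paste0("cw_", base),
               if (!is_catch) paste0("dw2_", base), paste0("resp_", base))
    onsets <- c(dw1, cw, if (!is_catch) dw2, resp)
    durs <- c(rep(stim_duration, length(onsets) - 1L), response_duration)
    ev[[i]] <- data.frame(onset = onsets, duration = durs, trial_type = types,
                          trial = i, condition = cond[i], stringsAsFactors = FALSE)
  }
  events <- if (n_trials) do.call(rbind, ev) else
    data.frame(onset = numeric(0), duration = numeric(0),
               trial_type = character(0), trial = integer(0),
               condition = character(0), stringsAsFactors = FALSE)
  total <- t + 10  # tail to capture the last BOLD responses
  structure(events,
            class = c("event_schedule", "data.frame"),
            trials = if (n_trials) do.call(rbind, tri) else NULL,
            tr = tr,
            total_duration = total,
            n_scans = as.integer(ceiling(total / tr)),
            intervals = all_intervals)
}

#' Write schedule events as a BIDS-style events table
#'
#' @param schedule An `event_schedule`.
#' @param path Output path (tab-separated: onset, duration, trial_type).
#' @return `path`, invisibly.
#' @export
write_events <- function(schedule, path) {
  utils::write.table(schedule[, c("onset", "duration", "trial_type")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an events table written by [write_events()]
#'
#' @param path Tab-separated events file with onset, duration, trial_type.
#' @param tr Repetition time to attach (seconds).
#' @return An `event_schedule` data frame (without the per-trial table).
#' @export
read_events <- function(path, tr = 2) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  total <- max(ev$onset + ev$duration) + 10
  structure(ev, class = c("event_schedule", "data.frame"), tr = tr,
            total_duration = total, n_scans = as.integer(ceiling(total / tr)))
}
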