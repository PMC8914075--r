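#' Logarithmically spaced filterbank
#'
#' Band edges geometrically spaced between `low` and `high`, approximating
#' the cochlear frequency map. The default 9 bands span 100-10,000 Hz.
#'
#' @param low,high Span in Hz, `0 < low < high`.
#' @param n Number of contiguous bands.
#' @return A `filterbank`: data frame with columns `low` and `high` (Hz).
#' @export
build_filterbank <- function(low = 100, high = 10000, n = 9L) {
  if (!(low > 0 && high > low)) stop("need 0 < low < high")
  if (n < 1L) stop("need at least one band")
  edges <- low * (high / low)^(seq(0, n) / n)
  structure(data.frame(low = edges[-(n + 1L)], high = edges[-1L]),
            class = c("filterbank", "data.frame"))
}

# Analytic-signal magnitude via the frequency-domain Hilbert construction.
analytic_magnitude <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

#' Wideband envelope of a waveform
#'
#' Band-pass filters the signal in each filterbank band (4th-order
#' Butterworth, zero-phase forward-backward), takes the magnitude of each
#' band's analytic signal, and sums across bands.
#'
#' @param wave A [waveform()] with `rate > 2 * max(fb$high)`.
#' @param fb A [build_filterbank()] object.
#' @return An `envelope`: non-negative numeric vector with attribute `rate`.
#' @export
wideband_envelope <- function(wave, fb = build_filterbank()) {
  stopifnot(inherits(wave, "waveform"), inherits(fb, "filterbank"))
  nyq <- wave$rate / 2
  if (max(fb$high) >= nyq)
    stop("sampling rate too low for the top filterbank band (Nyquist ", nyq, " Hz)")
  env <- numeric(length(wave$samples))
  for (b in seq_len(nrow(fb))) {
    bf <- signal::butter(2, c(fb$low[b], fb$high[b]) / nyq, type = "pass")
    band <- signal::filtfilt(bf, wave$samples)  # order doubles: 4th-order zero-phase
    env <- env + analytic_magnitude(band)
  }
  structure(env, class = "envelope", rate = wave$rate)
}

#' Resample an envelope to a lower rate
#'
#' Envelopes are smooth, so plain linear interpolation onto the new time
#' grid is adequate; used to bring envelopes to 1 kHz before the lag search.
#'
#' @param env An `envelope`.
#' @param rate Target rate in Hz.
#' @return The resampled `envelope`.
#' @export
resample_envelope <- function(env, rate = 1000) {
  stopifnot(inherits(env, "envelope"))
  r0 <- attr(env, "rate")
  if (rate >= r0) return(env)
  t_old <- (seq_along(env) - 1) / r0
  t_new <- seq(0, t_old[length(t_old)], by = 1 / rate)
  structure(stats::approx(t_old, as.numeric(env), xout = t_new)$y,
            class = "envelope", rate = rate)
}

#' Maximum lagged correlation between two envelopes
#'
#' Cross-correlates two envelopes over integer lags in
#' `[-max_lag, max_lag]`, computing the Pearson correlation on the valid
#' overlap at each lag (lags leaving less than `min_overlap` of the shorter
#' envelope are skipped), and returns the maximum with its lag. Ties are
#' broken toward the smallest `|lag|`.
#'
#' A positive lag means `b` is delayed relative to `a`.
#'
#' @param a,b `envelope` objects (or plain numeric vectors) at a common rate.
#' @param max_lag Maximum absolute lag in samples; default 25% of the
#'   shorter envelope.
#' @param min_overlap Minimum valid-overlap fraction of the shorter series.
#' @return An `envelope_similarity`: list with `max_corr` and `lag`.
#' @export
max_lagged_correlation <- function(a, b, max_lag = NULL, min_overlap = 0.5) {
  a <- as.numeric(a); b <- as.numeric(b)
  n_short <- min(length(a), length(b))
  if (n_short < 3L) stop("envelopes too short to correlate")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("constant envelope: correlation undefined")
  if (is.null(max_lag)) max_lag <- floor(0.25 * n_short)
  lags <- seq.int(-max_lag, max_lag)
  lags <- lags[order(abs(lags), lags)]  # smallest |lag| first for tie-breaks
  best_r <- -Inf; best_lag <- 0L
  for (L in lags) {
    lo <- max(1L, 1L - L); hi <- min(length(a), length(b) - L)
    if (hi - lo + 1L < max(3L, ceiling(min_overlap * n_short))) next
    ia <- seq.int(lo, hi)
    ib <- ia + L
    sa <- a[ia]; sb <- b[ib]
    if (stats::sd(sa) == 0 || stats::sd(sb) == 0) next
    r <- stats::cor(sa, sb)
    if (r > best_r + 1e-15) { best_r <- r; best_lag <- L }
  }
  if (!is.finite(best_r)) stop("no lag had sufficient overlap")
  structure(list(max_corr = best_r, lag = best_lag), class = "envelope_similarity")
}

#' @export
print.envelope_similarity <- function(x, ...) {
  cat(sprintf("<envelope similarity: max r = %.4f at lag %d>\n", x$max_corr, x$lag))
  invisible(x)
}

#' Envelope similarity between a clear and a degraded waveform
#'
#' Convenience wrapper: computes both wideband envelopes, resamples them to
#' `env_rate`, and returns the maximum lagged correlation.
#'
#' @param clear,degraded [waveform()] objects at a common rate.
#' @param fb Filterbank; defaults to 9 log-spaced bands over 100-10,000 Hz.
#' @param env_rate Envelope rate before the lag search (Hz); `NULL` skips
#'   resampling.
#' @param max_lag Passed to [max_lagged_correlation()].
#' @return An `envelope_similarity`.
#' @export
envelope_similarity <- function(clear, degraded, fb = build_filterbank(),
                                env_rate = 1000, max_lag = NULL) {
  ea <- wideband_envelope(clear, fb)
  eb <- wideband_envelope(degraded, fb)
  if (!is.null(env_rate)) {
    ea <- resample_envelope(ea, env_rate)
    eb <- resample_envelope(eb, env_rate)
  }
  max_lagged_correlation(ea, eb, max_lag = max_lag)
}

#' Spearman rank correlation
#'
#' Rank correlation with mid-rank ties and a two-sided p value; used to
#' relate envelope similarity to per-pseudoword repetition accuracy.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return A [stat_result()] with `statistic` = rho.
#' @export
rank_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  stat_result(statistic = unname(ct$estimate), df = length(x) - 2L,
              p = ct$p.value, effect = list(n = length(x)),
              method = "Spearman rank correlation")
}
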