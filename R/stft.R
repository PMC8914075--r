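#' STFT analysis parameters
#'
#' Settings for the short-time Fourier analysis used by the degradation
#' stage. The defaults (20 ms Gaussian window, 5 ms hop, floor 80 dB below
#' the spectrogram maximum) give formant-scale spectral resolution for
#' speech-like material while keeping the analysis invertible.
#'
#' @param window_length Analysis window length in seconds.
#' @param hop Hop between successive frames in seconds; `0 < hop <= window_length`.
#' @param window_shape One of `"gaussian"`, `"hann"`, `"hamming"`, `"rect"`.
#' @param log_floor Spectrogram floor in dB relative to the maximum (negative).
#' @return An object of class `stft_params`.
#' @export
stft_params <- function(window_length = 0.020, hop = 0.005,
                        window_shape = c("gaussian", "hann", "hamming", "rect"),
                        log_floor = -80) {
  window_shape <- match.arg(window_shape)
  if (!(hop > 0 && hop <= window_length))
    stop("hop must satisfy 0 < hop <= window_length")
  if (!is.finite(log_floor) || log_floor >= 0)
    stop("log_floor must be a finite negative dB value")
  structure(list(window_length = window_length, hop = hop,
                 window_shape = window_shape, log_floor = log_floor),
            class = "stft_params")
}

# Taper of n samples. Gaussian uses the alpha = 2.5 convention (std of the
# Gaussian = (n-1)/(2*alpha) samples).
stft_window <- function(shape, n) {
  k <- seq_len(n) - 1
  switch(shape,
    gaussian = exp(-0.5 * (2.5 * (k - (n - 1) / 2) / ((n - 1) / 2))^2),
    hann = 0.5 - 0.5 * cos(2 * pi * k / (n - 1)),
    hamming = 0.54 - 0.46 * cos(2 * pi * k / (n - 1)),
    rect = rep(1, n),
    stop("unknown window shape: ", shape)
  )
}

# Complex one-sided STFT: rows = frequency bins 0..floor(n/2), columns = frames.
stft_matrix <- function(x, window, hop_samples) {
  win <- length(window)
  n_frames <- 1L + (length(x) - win) %/% hop_samples
  idx <- outer(seq_len(win), (seq_len(n_frames) - 1L) * hop_samples, `+`)
  frames <- matrix(x[idx], nrow = win) * window
  S <- stats::mvfft(frames)
  S[seq_len(win %/% 2L + 1L), , drop = FALSE]
}

# Rebuild the full conjugate-symmetric spectrum from a one-sided matrix.
full_spectrum <- function(S_half, nfft) {
  n_half <- nrow(S_half)
  if (nfft %% 2L == 0L) {
    lower <- Conj(S_half[seq(n_half - 1L, 2L), , drop = FALSE])
  } else {
    lower <- Conj(S_half[seq(n_half, 2L), , drop = FALSE])
  }
  rbind(S_half, lower)
}

# Weighted overlap-add inverse of a full complex STFT matrix.
istft_matrix <- function(S_full, window, hop_samples) {
  nfft <- nrow(S_full)
  n_frames <- ncol(S_full)
  frames <- Re(stats::mvfft(S_full, inverse = TRUE)) / nfft
  out_len <- (n_frames - 1L) * hop_samples + nfft
  num <- numeric(out_len)
  den <- numeric(out_len)
  w2 <- window^2
  for (t in seq_len(n_frames)) {
    pos <- (t - 1L) * hop_samples + seq_len(nfft)
    num[pos] <- num[pos] + frames[, t] * window
    den[pos] <- den[pos] + w2
  }
  num / pmax(den, 1e-8 * max(den))
}

#' Log-amplitude spectrogram
#'
#' Computes the one-sided STFT magnitude in dB relative to the spectrogram
#' maximum, floored at `stft$log_floor`. The absolute reference level is
#' kept as an attribute so that inversion can restore the original scale.
#'
#' @param wave A [waveform()] at least one analysis window long.
#' @param stft [stft_params()].
#' @return A `log_spectrogram`: a frequency-by-time matrix of dB values (max
#'   0) with attributes `freq_step` (Hz per row), `time_step` (s per
#'   column), `rate`, `window`, `hop_samples`, `log_floor` and `ref_db`.
#' @export
log_spectrogram <- function(wave, stft = stft_params()) {
  stopifnot(inherits(wave, "waveform"), inherits(stft, "stft_params"))
  win <- max(2L, round(stft$window_length * wave$rate))
  hop <- max(1L, round(stft$hop * wave$rate))
  if (length(wave$samples) < win)
    stop("waveform shorter than one analysis window (", win, " samples)")
  window <- stft_window(stft$window_shape, win)
  S <- stft_matrix(wave$samples, window, hop)
  db <- 20 * log10(Mod(S))
  ref <- suppressWarnings(max(db))
  if (!is.finite(ref)) {          # silence: magnitude identically zero
    vals <- matrix(stft$log_floor, nrow(db), ncol(db))
    ref <- -Inf
  } else {
    vals <- pmax(db - ref, stft$log_floor)
  }
  structure(vals,
            class = "log_spectrogram",
            freq_step = wave$rate / win,
            time_step = hop / wave$rate,
            rate = wave$rate,
            window = window,
            hop_samples = hop,
            log_floor = stft$log_floor,
            ref_db = ref)
}

#' Invert a log spectrogram back to a waveform
#'
#' Griffin-Lim style alternating projection: starting from seeded random
#' phases, iteratively overlap-add synthesise, re-analyse, and replace the
#' magnitude with the target while keeping the estimated phase, with a
#' momentum (fast Griffin-Lim) extrapolation to speed convergence. The
#' best (lowest-error) iterate seen so far is retained and returned, so
#' the reported reconstruction error is non-increasing across iterations.
#' Values at the spectrogram floor are treated as zero magnitude so that
#' floor noise is not amplified.
#'
#' @param spec A `log_spectrogram`.
#' @param iters Number of projection iterations (>= 1).
#' @param seed Integer seed for the random phase initialisation.
#' @param init `"random"` (default) or `"zero"` phase start.
#' @param momentum Fast Griffin-Lim extrapolation coefficient in `[0, 1)`;
#'   0 recovers the plain alternating projection.
#' @return A [waveform()] of length `(frames - 1) * hop + window` samples,
#'   with attribute `reconstruction_error`: the per-iteration relative
#'   magnitude error of the best iterate so far.
#' @export
invert_spectrogram <- function(spec, iters = 64L, seed = 1L,
                               init = c("random", "zero"), momentum = 0.99) {
  stopifnot(inherits(spec, "log_spectrogram"))
  init <- match.arg(init)
  if (iters < 1L) stop("iters must be >= 1")
  window <- attr(spec, "window")
  hop <- attr(spec, "hop_samples")
  rate <- attr(spec, "rate")
  nfft <- length(window)
  ref <- attr(spec, "ref_db")
  floor_db <- attr(spec, "log_floor")
  vals <- unclass(spec)
  if (!is.finite(ref)) {
    out_len <- (ncol(vals) - 1L) * hop + nfft
    w <- waveform(numeric(out_len) + 0, rate)
    attr(w, "reconstruction_error") <- rep(0, iters)
    return(w)
  }
  mag <- 10^((vals + ref) / 20)
  mag[vals <= floor_db + 1e-12] <- 0
  mag_norm <- sqrt(sum(mag^2))

  if (init == "random") {
    set.seed(as.integer(seed))
    phase <- matrix(stats::runif(length(mag), -pi, pi), nrow(mag))
  } else {
    phase <- matrix(0, nrow(mag), ncol(mag))
  }
  err <- numeric(iters)
  best_err <- Inf
  best_S <- NULL
  C_prev <- mag * exp(1i * phase)   # projected iterate
  S_syn <- C_prev                   # extrapolated iterate used for synthesis
  for (it in seq_len(iters)) {
    x <- istft_matrix(full_spectrum(S_syn, nfft), window, hop)
    S_new <- stft_matrix(x, window, hop)
    e <- sqrt(sum((Mod(S_new) - mag)^2)) / max(mag_norm, .Machine$double.eps)
    C_cur <- mag * exp(1i * Arg(S_new))
    if (e < best_err) { best_err <- e; best_S <- C_cur }
    err[it] <- best_err
    S_syn <- C_cur + momentum * (C_cur - C_prev)
    C_prev <- C_cur
  }
  x <- istft_matrix(full_spectrum(best_S, nfft), window, hop)
  w <- waveform(x, rate)
  attr(w, "reconstruction_error") <- err
  w
}
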