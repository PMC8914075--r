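#' Construct a waveform
#'
#' A waveform is the unit passed through the degradation and envelope
#' stages: a finite, non-empty amplitude series (nominally in `[-1, 1]`)
#' together with its sampling rate in Hz.
#'
#' @param samples Numeric vector of amplitudes.
#' @param rate Sampling frequency in Hz (positive scalar).
#' @return An object of class `waveform` with fields `samples` and `rate`.
#' @export
waveform <- function(samples, rate) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("waveform must contain at least one sample")
  if (!all(is.finite(samples))) stop("waveform samples must be finite")
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("sampling rate must be a positive finite scalar")
  structure(list(samples = samples, rate = as.numeric(rate)), class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %d samples @ %g Hz (%.3f s), RMS %.4g>\n",
              length(x$samples), x$rate, length(x$samples) / x$rate, wave_rms(x)))
  invisible(x)
}

#' @export
length.waveform <- function(x) length(x$samples)

#' Duration of a waveform in seconds
#' @param wave A `waveform`.
#' @return Duration in seconds.
#' @export
wave_duration <- function(wave) length(wave$samples) / wave$rate

#' Root-mean-square amplitude
#' @param wave A `waveform`.
#' @return The RMS amplitude of the samples.
#' @export
wave_rms <- function(wave) sqrt(mean(wave$samples^2))

#' Normalize a waveform to a target RMS amplitude
#'
#' All stimuli are equalised to the same root-mean-square amplitude before
#' degradation and again after spectrogram inversion, so that clear and
#' degraded pseudowords are presented at matched energy.
#'
#' @param wave A `waveform` with non-zero energy.
#' @param target_rms Desired RMS amplitude (positive).
#' @return The rescaled `waveform`; length and rate are untouched.
#' @export
rms_normalize <- function(wave, target_rms) {
  stopifnot(inherits(wave, "waveform"))
  if (!is.numeric(target_rms) || length(target_rms) != 1L || target_rms <= 0)
    stop("target_rms must be a positive scalar")
  r <- wave_rms(wave)
  if (r == 0) stop("cannot normalize a silent (zero-energy) waveform")
  waveform(wave$samples * (target_rms / r), wave$rate)
}
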