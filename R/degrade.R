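#' Degradation parameters
#'
#' @param lower_frac,upper_frac Masked power band as fractions of the
#'   maximum modulation-spectrum power (defaults 0.70-0.75).
#' @param stft [stft_params()] used for analysis and re-synthesis.
#' @param inversion_iters Griffin-Lim iterations for spectrogram inversion.
#' @param target_rms RMS amplitude applied before analysis and restored
#'   after synthesis, so clear and degraded versions are energy matched.
#' @param mask_scale,dynamic_range Relative-power scale for the band, see
#'   [power_mask()].
#' @return An object of class `degradation_params`.
#' @export
degradation_params <- function(lower_frac = 0.70, upper_frac = 0.75,
                               stft = stft_params(), inversion_iters = 128L,
                               target_rms = 0.1, mask_scale = "db",
                               dynamic_range = 100) {
  if (!(lower_frac >= 0 && lower_frac <= upper_frac && upper_frac <= 1))
    stop("band must satisfy 0 <= lower_frac <= upper_frac <= 1")
  if (inversion_iters < 1L) stop("inversion_iters must be >= 1")
  if (target_rms <= 0) stop("target_rms must be positive")
  structure(list(lower_frac = lower_frac, upper_frac = upper_frac,
                 stft = stft, inversion_iters = as.integer(inversion_iters),
                 target_rms = target_rms, mask_scale = mask_scale,
                 dynamic_range = dynamic_range),
            class = "degradation_params")
}

#' Degrade a waveform by modulation filtering
#'
#' Reduces intelligibility by zeroing the intermediate-power band of the
#' modulation power spectrum: the waveform is RMS-normalised, its
#' log-amplitude spectrogram and 2D Fourier transform (MPS) computed, all
#' coefficients with power within `[lower_frac, upper_frac]` of the maximum
#' set to zero, the modified MPS back-transformed, and the resulting
#' spectrogram inverted to audio by iterative phase reconstruction. The
#' output is trimmed or zero-padded to the input length and RMS-normalised
#' to `params$target_rms`.
#'
#' With `lower_frac == upper_frac` the band is empty in practice and the
#' chain reduces to an analysis/resynthesis round trip.
#'
#' @param wave Input [waveform()].
#' @param params [degradation_params()].
#' @param seed Seed for the phase initialisation of the inversion.
#' @return The degraded [waveform()], same length and rate as the input.
#' @export
degrade <- function(wave, params = degradation_params(), seed = 1L) {
  stopifnot(inherits(wave, "waveform"), inherits(params, "degradation_params"))
  n_in <- length(wave$samples)
  w <- rms_normalize(wave, params$target_rms)
  spec <- log_spectrogram(w, params$stft)
  mps <- compute_mps(spec)
  if (params$lower_frac < params$upper_frac) {
    mask <- power_mask(mps, params$lower_frac, params$upper_frac,
                       scale = params$mask_scale,
                       dynamic_range = params$dynamic_range)
    mps <- apply_mask(mps, mask)
  }
  spec_mod <- invert_mps(mps)
  out <- invert_spectrogram(spec_mod, iters = params$inversion_iters, seed = seed)
  s <- out$samples
  if (length(s) >= n_in) s <- s[seq_len(n_in)] else s <- c(s, numeric(n_in - length(s)))
  if (sqrt(mean(s^2)) == 0) stop("degradation produced a silent waveform")
  rms_normalize(waveform(s, wave$rate), params$target_rms)
}
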