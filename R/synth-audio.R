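# Formant-based pseudoword synthesis: a stand-in corpus of 2-syllabic
# consonant-vowel pseudowords with speech-like spectrotemporal structure
# (glottal pulse source, cascade formant resonators, noise consonants).

# Steady-state vowel formants (Hz), classic American-English averages.
VOWEL_FORMANTS <- list(
  a = c(730, 1090, 2440),
  e = c(530, 1840, 2480),
  i = c(270, 2290, 3010),
  o = c(570,  840, 2410),
  u = c(300,  870, 2240)
)

# Consonants as band-limited noise bursts (low Hz, high Hz, relative level).
CONSONANT_BANDS <- list(
  s = c(3500, 8000, 1.0), f = c(1500, 7000, 0.6), t = c(2500, 6000, 0.9),
  k = c(1000, 4000, 0.9), p = c( 400, 2000, 0.9), m = c( 150, 1200, 0.7),
  n = c( 200, 1800, 0.7), l = c( 250, 2500, 0.7)
)

#' Pseudoword synthesis specification
#'
#' Describes a consonant-vowel pseudoword: per syllable a consonant label,
#' a vowel label and optional formant-track override.
#'
#' @param syllables List of syllables, each a list with `consonant`, `vowel`
#'   and optionally `formants` (numeric length-3 `(F1,F2,F3)` start values),
#'   `formants_end` (glide targets; default steady), `dur_weight` (relative
#'   syllable duration, default 1), `cons_frac` (consonant share of the
#'   syllable, default 0.22), `gain` (relative syllable level, default 1)
#'   and `gap_frac` (trailing silence share, default 0.05). The timing
#'   fields give each pseudoword its own temporal envelope shape.
#' @param duration Total duration in seconds.
#' @param f0 Fundamental frequency in Hz.
#' @param rate Sampling rate in Hz (default 44100).
#' @return A `pseudoword_spec`.
#' @export
pseudoword_spec <- function(syllables, duration = 0.8, f0 = 100, rate = 44100) {
  stopifnot(length(syllables) >= 1L, duration > 0, f0 > 0, rate > 0)
  syllables <- lapply(syllables, function(s) {
    if (is.null(s$formants)) s$formants <- VOWEL_FORMANTS[[s$vowel]]
    if (is.null(s$formants)) stop("unknown vowel: ", s$vowel)
    if (is.null(s$formants_end)) s$formants_end <- s$formants
    if (is.null(s$dur_weight)) s$dur_weight <- 1
    if (is.null(s$cons_frac)) s$cons_frac <- 0.22
    if (is.null(s$gain)) s$gain <- 1
    if (is.null(s$gap_frac)) s$gap_frac <- 0.05
    if (!(s$consonant %in% names(CONSONANT_BANDS)))
      stop("unknown consonant: ", s$consonant)
    s
  })
  structure(list(syllables = syllables, duration = duration, f0 = f0,
                 rate = rate),
            class = "pseudoword_spec")
}

#' Draw a random pseudoword specification
#'
#' @param seed Integer seed.
#' @param n_syllables Number of CV syllables (default 2).
#' @param duration,f0,rate Passed to [pseudoword_spec()].
#' @return A `pseudoword_spec` with attribute `phonemes`: the character
#'   vector of phoneme labels (consonant, vowel per syllable).
#' @export
random_pseudoword_spec <- function(seed, n_syllables = 2L, duration = 0.8,
                                   f0 = 100, rate = 44100) {
  set.seed(as.integer(seed))
  sylls <- lapply(seq_len(n_syllables), function(i) {
    list(consonant = sample(names(CONSONANT_BANDS), 1L),
         vowel = sample(names(VOWEL_FORMANTS), 1L),
         dur_weight = stats::runif(1, 0.6, 1.4),
         cons_frac = stats::runif(1, 0.12, 0.32),
         gain = stats::runif(1, 0.55, 1),
         gap_frac = stats::runif(1, 0, 0.18))
  })
  spec <- pseudoword_spec(sylls, duration = duration, f0 = f0, rate = rate)
  attr(spec, "phonemes") <- unlist(lapply(sylls, function(s) c(s$consonant, s$vowel)))
  spec
}

# Cascade of 3 two-pole resonators with linearly gliding centre frequencies.
formant_cascade <- function(x, f_start, f_end, bw, rate) {
  n <- length(x)
  glide <- seq(0, 1, length.out = n)
  y <- x
  for (k in seq_along(f_start)) {
    f <- f_start[k] + (f_end[k] - f_start[k]) * glide
    r <- exp(-pi * bw[k] / rate)
    theta <- 2 * pi * f / rate
    a1 <- 2 * r * cos(theta)
    a2 <- -r * r
    b0 <- 1 - r
    out <- numeric(n)
    y1 <- 0; y2 <- 0
    for (i in seq_len(n)) {
      v <- b0 * y[i] + a1[i] * y1 + a2 * y2
      out[i] <- v
      y2 <- y1; y1 <- v
    }
    y <- out
  }
  y
}

#' Synthesise a pseudoword waveform
#'
#' Each syllable is a noise-burst consonant followed by a voiced vowel:
#' glottal pulse train at `f0` with a lowpass glottal tilt and a
#' differentiating radiation term, passed through a cascade of three
#' formant resonators.
#' Output is RMS-normalised to 0.1 and exactly
#' `round(duration * rate)` samples long. Deterministic for a given
#' spec and seed.
#'
#' @param spec A [pseudoword_spec()].
#' @param seed Integer seed (consonant noise).
#' @return A [waveform()] at `spec$rate`.
#' @export
synth_pseudoword <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "pseudoword_spec"))
  rate <- spec$rate
  nyq <- rate / 2
  for (s in spec$syllables)
    if (max(s$formants, s$formants_end) >= nyq)
      stop("formant frequency at or above Nyquist (", nyq, " Hz)")
  set.seed(as.integer(seed))
  n_total <- round(spec$duration * rate)
  n_syll <- length(spec$syllables)
  wts <- vapply(spec$syllables, `[[`, numeric(1), "dur_weight")
  n_alloc <- floor(n_total * wts / sum(wts))
  n_alloc[n_syll] <- n_total - sum(n_alloc[-n_syll])
  out <- numeric(0)
  for (si in seq_len(n_syll)) {
    s <- spec$syllables[[si]]
    n_gap <- round(s$gap_frac * n_alloc[si])
    n_this <- n_alloc[si] - n_gap
    n_cons <- round(s$cons_frac * n_this)
    n_vow <- n_this - n_cons

    band <- CONSONANT_BANDS[[s$consonant]]
    bf <- signal::butter(2, pmin(band[1:2], nyq * 0.98) / nyq, type = "pass")
    noise <- as.numeric(signal::filter(bf, stats::rnorm(n_cons)))
    noise <- noise * band[3] * sin(pi * seq_len(n_cons) / n_cons)  # burst envelope

    # glottal source: impulse train -> two-pole lowpass -> differentiation
    src <- numeric(n_vow)
    period <- rate / spec$f0
    src[pmin(n_vow, unique(round(seq(1, n_vow, by = period))))] <- 1
    src <- as.numeric(signal::filter(signal::Arma(b = 1, a = c(1, -0.98)), src))
    src <- c(src[1], diff(src))
    voiced <- formant_cascade(src, s$formants, s$formants_end,
                              bw = c(80, 90, 120), rate = rate)
    ramp <- pmin(1, seq_len(n_vow) / (0.02 * rate),
                 (n_vow - seq_len(n_vow) + 1) / (0.06 * rate))
    voiced <- voiced * ramp
    # equalise segment loudness before concatenation
    if (sqrt(mean(noise^2)) > 0) noise <- noise * 0.4 / sqrt(mean(noise^2))
    if (sqrt(mean(voiced^2)) > 0) voiced <- voiced / sqrt(mean(voiced^2))
    out <- c(out, s$gain * c(noise, voiced), numeric(n_gap))
  }
  rms_normalize(waveform(out, rate), 0.1)
}
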