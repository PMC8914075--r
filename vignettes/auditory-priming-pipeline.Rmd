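---
title: "Methods: modulation-filtered speech degradation and the synthetic priming study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modulation-filtered speech degradation and the synthetic priming study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speechprime)
```

This vignette documents the models, the tunable parameters, and the design
choices behind `speechprime`. The package implements the computational
chain of a degraded–clear–degraded (DW1 → CW → DW2) auditory priming
experiment on fully synthetic data: audio degradation by modulation
filtering, envelope-similarity prediction of intelligibility, behavioral
scoring, and event-related BOLD group statistics.

## 1. Stimulus degradation by modulation filtering

A waveform is RMS-normalised, its log-amplitude spectrogram computed, the
2D Fourier transform taken to obtain the modulation power spectrum (MPS,
indexed by temporal modulation in Hz and spectral modulation in
cycles/kHz), a band of coefficients zeroed, the modified MPS
back-transformed, and the resulting magnitude spectrogram inverted to
audio by alternating projections.

**STFT settings.** A source corpus rarely documents its analysis settings,
so they are explicit parameters (`stft_params()`): Gaussian window of
20 ms, hop 5 ms, log floor at −80 dB relative to the spectrogram maximum.
A 20 ms window resolves formant structure (≈50 Hz rows at 44.1 kHz) while
the 5 ms hop supports temporal modulations up to 100 Hz; −80 dB is below
any perceptually relevant energy for RMS-normalised speech.

**The 70–75% power band.** The degradation deletes coefficients of
*intermediate* power: the strongest coefficients (the MPS core near zero
modulation, carrying formant structure) survive, as does the weak fringe.
Measured on real spectrograms the raw coefficient powers span many orders
of magnitude — the DC coefficient exceeds every other coefficient roughly
a hundred-fold, so a band defined as a *linear* fraction of the maximum
power is empty for any realistic audio and would leave the stimulus
untouched. `power_mask()` therefore measures relative power on the
decibel scale over a fixed 100 dB dynamic range: a coefficient `d` dB
below the maximum has relative power `1 − d/100`, and the closed band
`[0.70, 0.75]` keeps the meaning "intermediate power anchored at the
maximum" while selecting a non-trivial annulus (coefficients 25–30 dB
below the peak). The literal linear rule remains available as
`power_mask(scale = "linear")`. Masks are automatically symmetric under
the conjugate pairing (conjugate coefficients share power), so inversion
stays real.

**Spectrogram inversion.** `invert_spectrogram()` is a Griffin–Lim
alternating projection with a momentum term (coefficient 0.99) and seeded
random phase initialisation; the lowest-error iterate is retained, so the
reported reconstruction error is non-increasing. Values at the log floor
are treated as zero magnitude so floor noise is not amplified. The default
of 128 iterations was chosen from measured convergence: on pure tones the
round-trip median spectrogram error falls below 1 dB by 128 iterations
(about 2 dB at 64), and on speech-like material an
analysis–masking-free–resynthesis round trip sits near 0.5 dB median. We
state 3 dB median as the round-trip tolerance for broadband material.
Output is trimmed/zero-padded to the input length (trial timing requires
fixed durations) and re-normalised to the target RMS.

**Degenerate inputs.** Silent input raises a zero-energy error at
normalisation; an all-floor spectrogram inverts to silence; an all-zero
MPS has no defined maximum and errors.

## 2. Envelope similarity

`wideband_envelope()` band-passes the signal in 9 logarithmically spaced
bands over 100–10,000 Hz (geometric edges, a coarse cochlear map), takes
each band's analytic-signal magnitude (FFT Hilbert construction), and
sums. Filters are 4th-order zero-phase Butterworth (forward–backward),
chosen so band filtering cannot distort envelope timing. Envelopes are
linearly resampled to 1 kHz before the lag search — they are smooth, so
interpolation is adequate and the search cost drops.

`max_lagged_correlation()` computes the Pearson correlation on the valid
overlap at each integer lag within ±25% of the shorter envelope (the
source study searched "across lags" without a stated range), requires at
least 50% overlap to avoid spurious maxima from tiny segments, and breaks
ties toward the smallest |lag|. On the synthetic corpus, matched
clear/degraded pairs exceed mismatched pairs on average but distributions
overlap — the property tests assert stochastic dominance, not separation.

## 3. Behavioral scoring

`score_response()` implements the three-level whole-pseudoword rule:
1 for a flawless repetition, 0.5 for exactly one incorrectly reported
phoneme, 0 otherwise (including missing responses). The number of
incorrect phonemes is the minimum edit distance between reference and
response at unit costs: how raters aligned phonemes is not documented, and
edit alignment treats insertions and omissions as the single errors a
human rater would count; strict positional counting is available via
`mode = "positional"`. Percentages are reported to one decimal.

## 4. The synthetic-data generators

These generators define the study conditions; their defaults are fixed,
not tuning knobs.

* **Pseudowords** (`synth_pseudoword()`): 2-syllable consonant–vowel
  words, 0.8 s at 44.1 kHz, f0 = 100 Hz; vowels as cascaded two-pole
  formant resonators over a pulse-train source with glottal tilt and
  radiation terms, consonants as band-limited noise bursts. Per-word
  timing diversity (syllable duration weights, consonant share, syllable
  gain, inter-syllable gaps) gives each word its own envelope shape —
  without it, matched and mismatched envelope similarities would be
  indistinguishable. What the generator does *not* emulate: articulatory
  coarticulation, prosody, speaker variability; passing tests show the
  pipeline's statistics behave correctly, not that the stimuli are
  perceptually equivalent to recorded speech.
* **Schedules** (`generate_schedule()`): 61 match, 61 mismatch and 12
  catch trials (split evenly between match/mismatch forms) in seeded
  pseudorandom order; every ISI/ITI drawn from a gamma law truncated by
  rejection to [3, 16] s; TR = 2 s. The gamma shape/scale are not
  documented for the source paradigm; shape 2, scale 2.5 place most mass
  inside the truncation window (truncated mean ≈ 5.9 s). Catch trials
  have no DW2; their DW1/CW onsets fold into the corresponding condition
  regressors.
* **Responses** (`simulate_responses()`): correct-repetition probability
  is `plogis(intercept + slope·similarity + subject effect)` on match
  trials (slope 8, intercept −2.4, subject SD 0.5) and a floor (0.02) on
  mismatch trials; incorrect responses are near-misses (one substitution,
  probability 0.5 on match and 0.03 on mismatch trials) or wholly wrong,
  and 13.6% of wholly incorrect mismatch responses repeat the clear word.
  These constants were calibrated once so the scored condition means land
  near 68% (match) and 3–4% (mismatch) with SDs of the observed order —
  the behavioral profile the paradigm produces — and are not adjusted
  thereafter.
* **BOLD** (`simulate_bold()`): voxel time series are HRF-convolved event
  regressors weighted by ROI amplitudes plus optional DCT drift and AR(1)
  Gaussian noise (default innovation SD 1, AR coefficient 0.3), with six
  motion-like random-walk nuisance series. The HRF is the canonical
  double-gamma (shapes 6 and 16, undershoot ratio 6, peak scaled to 1).
  The effect map gives every PAC ROI a stimulus amplitude of 1.58 with a
  DW2 match boost of 1.38, so condition means of position-averaged betas
  sit near 2.27 (match) and 1.58 (mismatch); DW1 amplitudes are equal
  across conditions by construction, because the trial type is unknown
  when DW1 plays. The atlas is an abstract 20×20×12 lattice with six
  block ROIs (Te1.0/Te1.1/Te1.2 × hemisphere) — no anatomy is implied.
  `smooth_noise_fields()` additionally provides spatially smooth Gaussian
  fields (FWHM 8/3 voxels, matching an 8 mm kernel on 3 mm voxels) used
  as realistic group-level null maps.

## 5. GLM and group inference

`build_design()` samples each event regressor as the sum of canonical
HRFs at scan times (events as impulses; modeled response durations do not
enter the convolution), appends nuisance series, a DCT drift basis
implementing the 128 s high-pass in regression form, and an intercept.
`fit_glm()` is voxelwise OLS; rank-deficient designs fall back to the
Moore–Penrose pseudo-inverse with a warning and `df = scans − rank`.
`f_contrast()` is the extra-sum-of-squares F; `conjunction_null()` is the
minimum-statistic conjunction (a voxel passes only if every component map
is individually significant, i.e. conjunction p = max of component p's).

**Cluster correction.** Random-field-theory cluster FWE requires
smoothness estimation that is out of scope here; `cluster_correct()`
instead uses sign-flip permutations of per-subject contrast maps: the
one-sample t map is thresholded at the two-sided voxel p (default 0.001),
suprathreshold voxels are clustered (26-connectivity default), and
cluster extents are compared with the permutation null of the maximum
extent. The test is exact under sign symmetry; on *smooth* null fields
its family-wise error sits near the nominal 5% (3–4% over 500
simulations, slightly conservative because cluster sizes are discrete),
while on voxelwise-independent noise it is strongly conservative —
suprathreshold voxels are then isolated and no extent is ever unusual.

**Repeated-measures ANOVA.** Group inference uses the summary-statistics
route: per-subject mean betas from ROI voxels selected by the
effects-of-interest F contrast at p < 0.001 uncorrected (a
condition-unbiased criterion that drops pure-noise voxels). `rm_anova()`
projects each subject's cell means onto orthonormal contrasts per effect
and forms the univariate within-subject F; it reproduces
`aov(... Error(subject/...))` exactly and adds a Greenhouse–Geisser
option (`gg = TRUE`, epsilon from the contrast-score covariance);
sphericity is uncorrected by default. The 2×2 position × condition
interaction has a closed form — the squared paired t on each subject's
difference-of-differences — which `rm_anova_2x2()` uses directly.
Post-hoc match-vs-mismatch paired t-tests are corrected by
Benjamini–Hochberg FDR (q = 0.05) across the six ROIs.

## 6. Problem sizes and verification scope

The test suite runs the full-scale study where it matters and smaller
problems where only calibration is at stake: the end-to-end replication
uses the complete design (20 subjects, 61/61/12 trials, 20×20×12 atlas)
with the DW2 boost removed from right Te1.2, and recovers the expected
pattern — a significant interaction, a significant condition main effect,
post-hoc rejections in exactly the five boosted ROIs, and no DW1
difference. Null calibration replicates use a 10×10×6 atlas and 20/20/4
schedules (10 replicates); cluster-FWE calibration uses 500 smooth-field
group datasets of 12 subjects at 200 permutations; degradation unit tests
run at 8–22.05 kHz. Determinism is exercised throughout: every stochastic
stage takes an explicit seed and reproduces bit-identical output.

## 7. Known limitations

* The degraded stimuli are not perceptually validated; the 70–75% band on
  the dB scale is a principled reading of an under-specified rule, and
  other readings (percentile bands, other dynamic ranges) would mask
  different coefficient sets.
* Spectrogram inversion is approximate; residual reconstruction error
  re-introduces a small amount of power into the masked band (the suite
  bounds it at <10% of the original band power).
* The BOLD simulator omits scanner drift nonstationarity, motion-signal
  coupling, and physiological noise; AR(1) is the only temporal
  correlation. Voxel selection and inference are validated against this
  generative model, not against real fMRI data.
* The permutation cluster test is conservative on unsmooth data, and the
  atlas is purely synthetic — no anatomical claims transfer.
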