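# Shared fixtures, built in code at test time.

# Short harmonic test waveform at a modest rate (fast STFT tests).
toy_wave <- function(n = 4000, rate = 8000) {
  t <- (seq_len(n) - 1) / rate
  waveform(0.5 * sin(2 * pi * 500 * t) + 0.2 * sin(2 * pi * 1250 * t) +
             0.1 * sin(2 * pi * 90 * t), rate)
}

# Compact STFT settings for low-rate fixtures.
toy_stft <- function() stft_params(window_length = 0.016, hop = 0.004)

# Small synthetic modulation spectrum with controlled coefficient powers:
# builds a real matrix from its half-spectrum so conjugate symmetry holds.
toy_mps <- function(values) {
  spec <- structure(values, class = "log_spectrogram",
                    freq_step = 10, time_step = 0.01, rate = 8000,
                    window = rep(1, 16), hop_samples = 4,
                    log_floor = -80, ref_db = 0)
  compute_mps(spec)
}

# Brute-force per-lag Pearson oracle for the lagged-correlation search.
bruteforce_max_lag_corr <- function(a, b, max_lag, min_overlap = 0.5) {
  n_short <- min(length(a), length(b))
  best <- NULL
  for (L in -max_lag:max_lag) {
    ia <- seq_len(length(a))
    ia <- ia[ia + L >= 1 & ia + L <= length(b)]
    if (length(ia) < max(3, ceiling(min_overlap * n_short))) next
    r <- suppressWarnings(cor(a[ia], b[ia + L]))
    if (!is.finite(r)) next
    if (is.null(best) || r > best$r + 1e-15 ||
        (abs(r - best$r) <= 1e-15 && abs(L) < abs(best$lag)))
      best <- list(r = r, lag = L)
  }
  best
}

# Per-subject roi beta table with known cell structure, for ANOVA tests.
toy_roi_table <- function(n_subjects, cond_effect = 0, noise_sd = 0.1,
                          seed = 1) {
  set.seed(seed)
  g <- expand.grid(subject = seq_len(n_subjects),
                   roi = c("Te1.0", "Te1.1", "Te1.2"),
                   hemisphere = c("L", "R"),
                   condition = c("match", "mismatch"),
                   position = c("dw1", "dw2"),
                   stringsAsFactors = FALSE)
  g$mean_beta <- rnorm(nrow(g), 0, noise_sd) +
    ifelse(g$condition == "match", cond_effect, 0)
  g
}
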