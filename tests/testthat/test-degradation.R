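# stimulus degradation chain: STFT, MPS, band masking, inversion.

test_that("log spectrogram matches a direct DFT-per-frame oracle", {
  set.seed(7)
  w <- waveform(rnorm(64), 1000)
  sp <- stft_params(window_length = 0.016, hop = 0.008, window_shape = "hann")
  spec <- log_spectrogram(w, sp)

  win <- 16L; hop <- 8L
  window <- 0.5 - 0.5 * cos(2 * pi * (0:(win - 1)) / (win - 1))
  n_frames <- 1 + (64 - win) %/% hop
  k <- 0:(win %/% 2)
  mags <- sapply(seq_len(n_frames), function(fr) {
    x <- w$samples[(fr - 1) * hop + 1:win] * window
    # direct DFT, one-sided
    sapply(k, function(kk) Mod(sum(x * exp(-2i * pi * kk * (0:(win - 1)) / win))))
  })
  db <- 20 * log10(mags)
  expected <- pmax(db - max(db), -80)
  expect_equal(unclass(spec), expected, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(dim(spec), c(win %/% 2 + 1, n_frames))
})

test_that("a bin-centered pure tone concentrates energy in its row", {
  rate <- 8000
  # rectangular window so a bin-centered tone has no spectral leakage
  sp <- stft_params(window_length = 0.016, hop = 0.004, window_shape = "rect")
  f <- 10 * rate / 128  # exactly bin 10 of the 128-sample window
  t <- (0:4095) / rate
  spec <- log_spectrogram(waveform(sin(2 * pi * f * t), rate), sp)
  lin <- 10^(unclass(spec) / 10)            # power ratios
  lin[unclass(spec) <= -80] <- 0
  row_energy <- rowSums(lin)
  expect_gt(row_energy[11] / sum(row_energy), 0.9)
})

test_that("silence maps to an all-floor spectrogram and near-silent inversion", {
  w <- waveform(rep(0, 2048), 8000)
  spec <- log_spectrogram(w, toy_stft())
  expect_true(all(unclass(spec) == -80))
  out <- invert_spectrogram(spec, iters = 4, seed = 1)
  expect_lt(wave_rms(out), 1e-6)
})

test_that("too-short waveforms and bad parameters error", {
  expect_error(log_spectrogram(waveform(1:10, 8000), toy_stft()), "shorter")
  expect_error(stft_params(hop = 0.05, window_length = 0.02), "hop")
  spec <- log_spectrogram(toy_wave(), toy_stft())
  expect_error(invert_spectrogram(spec, iters = 0), "iters")
})

test_that("MPS is an invertible conjugate-symmetric transform", {
  spec <- log_spectrogram(toy_wave(), toy_stft())
  mps <- compute_mps(spec)
  back <- invert_mps(mps)
  expect_lt(max(abs(unclass(back) - unclass(spec))), 1e-10)

  # conjugate symmetry: inverse transform is real
  expect_lt(max(abs(Im(stats::fft(unclass(mps), inverse = TRUE)))) /
              max(Mod(unclass(mps))), 1e-10)

  # constant spectrogram: all power in the DC coefficient
  const <- toy_mps(matrix(-3, 8, 10))
  p <- Mod(unclass(const))^2
  expect_equal(sum(p) - p[1, 1], 0, tolerance = 1e-18 * p[1, 1])

  # single ripple lands in exactly one conjugate pair (plus DC)
  g <- outer(seq_len(16), seq_len(12), function(i, j) -10 + cos(2 * pi * 3 * (j - 1) / 12))
  rip <- toy_mps(g)
  p <- Mod(unclass(rip))^2
  ord <- order(p, decreasing = TRUE)
  top <- arrayInd(ord[1:3], dim(p))
  expect_equal(top[1, ], c(1, 1))  # DC
  expect_setequal(top[2:3, 2], c(4, 10))  # temporal modulation +-3 cycles
  expect_lt(sum(p[ord[-(1:3)]]) / sum(p), 1e-20)

  # Parseval: total power equals n * squared norm of the matrix
  set.seed(3)
  m <- matrix(rnorm(64), 8, 8)
  mp <- toy_mps(m)
  expect_equal(sum(Mod(unclass(mp))^2), 64 * sum(m^2), tolerance = 1e-12)
})

test_that("power mask equals a brute-force comparison oracle", {
  # constructed powers: only the 0.72 coefficient pair is masked (linear)
  g <- outer(seq_len(12), seq_len(12), function(i, j)
    cos(2 * pi * 2 * (j - 1) / 12) + sqrt(0.72) * cos(2 * pi * 2 * (i - 1) / 12) +
      sqrt(0.5) * cos(2 * pi * 4 * (j - 1) / 12))
  mps <- toy_mps(g)
  p <- Mod(unclass(mps))^2
  mask <- power_mask(mps, 0.70, 0.75, scale = "linear")
  expect_identical(unclass(unclass(mask)),
                   !(p >= 0.70 * max(p) & p <= 0.75 * max(p)))
  expect_identical(sum(!mask), 2L)  # one conjugate pair

  # random small matrices, both scales, against independent recomputation
  for (i in 1:20) {
    set.seed(i)
    m <- toy_mps(matrix(rnorm(36), 6, 6))
    p <- Mod(unclass(m))^2
    lin <- power_mask(m, 0.70, 0.75, scale = "linear")
    expect_identical(unclass(unclass(lin)), !(p >= 0.7 * max(p) & p <= 0.75 * max(p)))
    db <- power_mask(m, 0.70, 0.75, scale = "db", dynamic_range = 100)
    frac <- 1 - 10 * log10(max(p) / p) / 100
    expect_identical(unclass(unclass(db)), !(frac >= 0.7 & frac <= 0.75))
    # symmetry under conjugate pairing
    for (msk in list(lin, db)) {
      mm <- unclass(unclass(msk))
      sym <- mm[c(1, 6:2), c(1, 6:2)]
      expect_identical(mm, sym)
    }
  }
})

test_that("mask edge cases behave as defined", {
  u <- toy_mps(matrix(-5, 4, 4))  # all power in DC: nothing in [0.7, 0.75]
  expect_true(all(power_mask(u, 0.70, 0.75, scale = "linear")))
  # full-band limit masks everything
  set.seed(1)
  m <- toy_mps(matrix(rnorm(16), 4, 4))
  expect_true(all(!power_mask(m, 0, 1, scale = "linear")))
  # all-zero spectrum is rejected
  z <- toy_mps(matrix(0, 4, 4))
  expect_error(power_mask(z), "undefined")
})

test_that("spectrogram inversion error is non-increasing and tones round-trip", {
  rate <- 8000
  sp <- stft_params(window_length = 0.016, hop = 0.004)
  t <- (0:4095) / rate
  w <- waveform(sin(2 * pi * 625 * t), rate)  # bin-centered at 128-sample window
  spec <- log_spectrogram(w, sp)

  one <- invert_spectrogram(spec, iters = 1, seed = 5)
  many <- invert_spectrogram(spec, iters = 128, seed = 5)
  err1 <- attr(one, "reconstruction_error")
  err_many <- attr(many, "reconstruction_error")
  expect_true(all(diff(err_many) <= 1e-9))
  expect_lte(err_many[128], err1[1])

  spec2 <- log_spectrogram(many, sp)
  expect_lt(median(abs(unclass(spec2) - unclass(spec))), 1)  # within 1 dB median
})

test_that("degrade with an empty band is an analysis/resynthesis round trip", {
  w <- toy_wave(4000, 8000)
  par <- degradation_params(lower_frac = 0.5, upper_frac = 0.5,
                            stft = toy_stft(), inversion_iters = 48)
  d <- degrade(w, par, seed = 2)
  expect_identical(length(d$samples), length(w$samples))
  expect_equal(wave_rms(d), par$target_rms, tolerance = 1e-6)
  s1 <- log_spectrogram(rms_normalize(w, par$target_rms), toy_stft())
  s2 <- log_spectrogram(d, toy_stft())
  expect_lt(median(abs(unclass(s1) - unclass(s2))), 3)  # stated 3 dB tolerance
})

test_that("degrade suppresses the masked band and is deterministic", {
  w <- synth_pseudoword(random_pseudoword_spec(5, rate = 22050), seed = 5)
  par <- degradation_params()
  d <- degrade(w, par, seed = 7)
  expect_identical(length(d$samples), length(w$samples))
  expect_equal(wave_rms(d), par$target_rms, tolerance = 1e-6)

  s1 <- log_spectrogram(rms_normalize(w, par$target_rms), par$stft)
  m1 <- compute_mps(s1)
  mask <- power_mask(m1, par$lower_frac, par$upper_frac)
  expect_gt(sum(!mask), 0)
  m2 <- compute_mps(log_spectrogram(d, par$stft))
  p1 <- Mod(unclass(m1))^2
  p2 <- Mod(unclass(m2))^2
  expect_lt(mean(p2[!mask]) / mean(p1[!mask]), 0.10)  # >= 90% suppression

  d2 <- degrade(w, par, seed = 7)
  expect_identical(d$samples, d2$samples)  # bit-identical under a fixed seed
})
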