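test_that("integer-cycle cropping aligns both rates on exact bins", {
  d <- make_design(6, 7.5, 2)
  m <- roi_montage()
  s <- flat_subject(c(0.3), noise = 1, seed = 2)
  rec <- simulate_subject_eeg(s, d, m, fs = 512)$recording
  segs <- preprocess(rec, d)
  cr <- crop_integer_cycles(segs)
  # 60 s plateau at 256 Hz: multiple of the 512-sample (2 s = 3 cycle) block
  expect_equal(nrow(cr$segments[[1]]), 15360)
  expect_equal(nrow(cr$segments[[1]]) %% 512, 0)
  sp <- fft_amplitude(cr$segments[[1]], cr$fs)
  df <- sp$fs / sp$n_samples
  expect_equal(round(df, 3), 0.017)            # high-resolution grid
  expect_silent(bin_at(sp, 6)); expect_silent(bin_at(sp, 7.5))
  expect_equal(sp$freqs[bin_at(sp, 6)], 6)
  expect_equal(sp$freqs[bin_at(sp, 7.5)], 7.5)
  # a segment of exactly one cycle block is returned unchanged
  d1 <- tiny_design(plateau = 2)
  rec1 <- simulate_subject_eeg(flat_subject(0.3, noise = 0, seed = 1), d1, m,
                               fs = 256)$recording
  cr1 <- crop_integer_cycles(preprocess(rec1, d1, target_fs = 256))
  expect_equal(nrow(cr1$segments[[1]]), 512)
})

test_that("per-condition averaging preserves coherent signal and cancels noise", {
  m <- roi_montage(); fs <- 64; n <- 4 * fs
  t <- (0:(n - 1)) / fs
  sig <- matrix(sin(2 * pi * 4 * t), n, nrow(m))
  noise <- matrix(rnorm(n * nrow(m)), n, nrow(m))
  segs <- fpvstag:::new_segments(list(sig + noise, sig - noise),
                                 c("a", "a"), fs, m, c(0, 4), tiny_design())
  avg <- average_condition(segs)
  expect_length(avg$segments, 1)
  expect_equal(avg$segments[[1]], sig, tolerance = 1e-12)
  # identical segments average to themselves
  segs2 <- fpvstag:::new_segments(list(sig, sig), c("a", "a"), fs, m,
                                  c(0, 4), tiny_design())
  expect_equal(average_condition(segs2)$segments[[1]], sig)
  # spectral noise floor shrinks ~ 1/sqrt(n_averaged)
  set.seed(3)
  floors <- vapply(c(1, 4, 16), function(k) {
    mats <- replicate(k, matrix(rnorm(n), n, 1), simplify = FALSE)
    sg <- fpvstag:::new_segments(mats, rep("a", k), fs,
                                 biosemi_montage("Oz"), c(0, 4), tiny_design())
    a <- average_condition(sg)
    mean(fft_amplitude(a$segments[[1]], fs)$amps[10:100, 1])
  }, 0)
  expect_equal(floors[1] / floors[2], 2, tolerance = 0.25)
  expect_equal(floors[2] / floors[3], 2, tolerance = 0.25)
})

test_that("fft_amplitude matches the direct DFT oracle to 1e-9", {
  set.seed(7)
  for (n in c(64, 101, 1024, 4096)) {
    x <- rnorm(n)
    ours <- fft_amplitude(x, fs = n)$amps[, 1]
    oracle <- oracle_dft_amplitude(x)
    expect_lt(max(abs(ours - oracle)) / max(oracle), 1e-9)
  }
  # closed forms: pure and superposed sinusoids on whole cycles
  fs <- 128; n <- 2 * fs; t <- (0:(n - 1)) / fs
  sp <- fft_amplitude(sin(2 * pi * 6 * t), fs)
  expect_equal(sp$amps[bin_at(sp, 6), 1], 1, tolerance = 1e-12)
  expect_lt(max(sp$amps[-bin_at(sp, 6), 1]), 1e-9)
  sp2 <- fft_amplitude(sin(2 * pi * 6 * t) + 0.5 * sin(2 * pi * 7.5 * t), fs)
  expect_equal(sp2$amps[bin_at(sp2, 6), 1], 1, tolerance = 1e-9)
  expect_equal(sp2$amps[bin_at(sp2, 7.5), 1], 0.5, tolerance = 1e-9)
  expect_true(all(fft_amplitude(rep(0, 256), 128)$amps == 0))
})

test_that("local noise bins match brute-force enumeration on random spectra", {
  set.seed(11)
  hood_defaults <- list(c(12, 2, 2), c(12, 2, 2), c(8, 2, 2), c(12, 4, 2),
                        c(12, 2, 4))
  for (case in seq_len(1000)) {
    pars <- hood_defaults[[(case %% length(hood_defaults)) + 1]]
    n <- 101
    a <- round(abs(rnorm(n)), 2)       # rounding provokes ties
    i <- sample(seq(pars[1] + 1, n - pars[1]), 1)
    hood <- noise_neighborhood(pars[1], pars[2], pars[3])
    ours <- fpvstag:::noise_stats_vec(a, i, hood)
    oracle_idx <- oracle_noise_bins(a, i, pars[1], pars[2], pars[3])
    expect_identical(sort(ours$indices), sort(oracle_idx))
    expect_equal(ours$mean, mean(a[oracle_idx]))
    expect_equal(ours$sd, sd(a[oracle_idx]))
  }
  expect_equal(noise_neighborhood()$n_bins, 20)
})

test_that("local noise handles flat and extreme-value neighbourhoods", {
  base <- rep(2, 101)
  sp <- structure(list(freqs = (0:100) * 0.1, amps = matrix(base, ncol = 1),
                       T = 10, n_samples = 200, fs = 20, labels = "a"),
                  class = "ft_spectrum")
  ln <- local_noise(sp, 5, noise_neighborhood())
  expect_equal(unname(ln$mean), 2); expect_equal(unname(ln$sd), 0)
  # one huge and one tiny non-adjacent neighbour are both excluded
  a2 <- rep(1, 101); a2[44] <- 100; a2[56] <- 0
  sp2 <- sp; sp2$amps <- matrix(a2, ncol = 1)
  ln2 <- local_noise(sp2, 5, noise_neighborhood())
  expect_equal(unname(ln2$mean), 1); expect_equal(unname(ln2$sd), 0)
  expect_error(local_noise(sp, 0.5, noise_neighborhood()), "edge")
})

test_that("SNR, baseline-corrected and z statistics follow their definitions", {
  mk_spec <- function(a) structure(
    list(freqs = (seq_along(a) - 1) * 0.1, amps = matrix(a, ncol = 1),
         T = 10, n_samples = 2 * (length(a) - 1), fs = 0.2 * (length(a) - 1),
         labels = "a"), class = "ft_spectrum")
  hood <- noise_neighborhood()
  flat <- mk_spec(rep(3, 101))
  expect_equal(unname(snr_spectrum(flat, 5, hood)$values[1, 1]), 1)
  expect_equal(unname(baseline_corrected(flat, 5, hood)$values[1, 1]), 0)
  a <- rep(1, 101); a[51] <- 5
  peak <- mk_spec(a)
  expect_equal(unname(snr_spectrum(peak, 5, hood)$values[1, 1]), 5)
  expect_equal(unname(baseline_corrected(peak, 5, hood)$values[1, 1]), 4)
  # z: amp = mean + 2 sd -> z = 2 (alternating neighbourhood, sd > 0)
  b <- rep(c(0.9, 1.1), 51)[1:101]
  st <- fpvstag:::noise_stats_vec(b, 51, hood)
  b[51] <- st$mean + 2 * st$sd
  expect_equal(unname(zscore_spectrum(mk_spec(b), 5, hood)$values[1, 1]), 2,
               tolerance = 1e-12)
  expect_error(zscore_spectrum(flat, 5, hood), "SD is zero")
})

test_that("baseline, SNR and z obey their algebraic relations and scaling", {
  set.seed(13)
  a <- abs(rnorm(201)) + 0.5
  sp <- structure(list(freqs = (0:200) * 0.1, amps = matrix(a, ncol = 1),
                       T = 10, n_samples = 400, fs = 40, labels = "a"),
                  class = "ft_spectrum")
  hood <- noise_neighborhood()
  freqs <- c(5, 8, 12)
  snr <- snr_spectrum(sp, freqs, hood)$values
  bc <- baseline_corrected(sp, freqs, hood)$values
  z <- zscore_spectrum(sp, freqs, hood)$values
  nm <- vapply(freqs, function(f) unname(local_noise(sp, f, hood)$mean), 0)
  # identity: baseline = noise_mean * (SNR - 1), exactly
  expect_equal(unname(bc[1, ]), unname(nm * (snr[1, ] - 1)), tolerance = 1e-12)
  # scaling by c: SNR and z invariant, baseline scales
  sp2 <- sp; sp2$amps <- sp$amps * 7
  expect_equal(snr_spectrum(sp2, freqs, hood)$values, snr, tolerance = 1e-12)
  expect_equal(zscore_spectrum(sp2, freqs, hood)$values, z, tolerance = 1e-12)
  expect_equal(baseline_corrected(sp2, freqs, hood)$values, 7 * bc,
               tolerance = 1e-12)
  # relabelling frequencies leaves values unchanged (amplitude-only statistics)
  sp3 <- sp; sp3$freqs <- sp$freqs * 2; sp3$fs <- sp$fs * 2
  expect_equal(snr_spectrum(sp3, freqs * 2, hood)$values[1, ],
               snr[1, ], ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("pure-noise z-scores have the tail the Monte-Carlo oracle predicts", {
  # The single-bin z statistic on Rayleigh amplitude bins is right-skewed and
  # the extreme-bin exclusion shrinks the local SD, so its z > 1.64 tail is
  # heavier than the nominal 5%: a 30k-draw oracle run gives 0.116.
  set.seed(17)
  hood <- noise_neighborhood()
  zs <- replicate(1000, {
    a <- sqrt(rnorm(61)^2 + rnorm(61)^2)     # Rayleigh amplitude bins
    s <- fpvstag:::noise_stats_vec(a, 31, hood)
    (a[31] - s$mean) / s$sd
  })
  fp <- mean(zs > 1.64)
  expect_equal(fp, 0.116, tolerance = 0.3)   # within ~3 MC SEs
  # median SNR of white-noise spectra is ~1
  snrs <- replicate(200, {
    a <- sqrt(rnorm(61)^2 + rnorm(61)^2)
    s <- fpvstag:::noise_stats_vec(a, 31, hood)
    a[31] / s$mean
  })
  expect_equal(median(snrs), 1, tolerance = 0.15)
})
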