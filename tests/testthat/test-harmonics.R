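# Synthetic grand-average spectrum: Rayleigh noise floor with peaks of given
# amplitude injected at chosen frequencies.
synthetic_grand <- function(peaks, floor_scale = 0.02, fs = 256, T = 60,
                            seed = 101) {
  set.seed(seed)
  n <- fs * T
  half <- floor(n / 2) + 1
  a <- floor_scale * sqrt(rnorm(half)^2 + rnorm(half)^2)
  freqs <- (seq_len(half) - 1) / T
  for (f in names(peaks)) a[round(as.numeric(f) * T) + 1] <- peaks[[f]]
  structure(list(freqs = freqs, amps = matrix(a, ncol = 1), T = T,
                 n_samples = n, fs = fs, labels = "grand"),
            class = "ft_spectrum")
}

test_that("group-level selection walks harmonics until the first failure", {
  # harmonics 1..5 of 6 Hz and 1..4 of 7.5 Hz strong -> both stop at 30 Hz
  peaks <- c(`6` = 1, `12` = 0.5, `18` = 0.25, `24` = 0.12, `30` = 0.3,
             `7.5` = 0.8, `15` = 0.4, `22.5` = 0.2)
  g <- synthetic_grand(as.list(peaks))
  s6 <- select_harmonics_group(g, 6)
  s75 <- select_harmonics_group(g, 7.5)
  expect_equal(s6$harmonics, c(6, 12, 18, 24, 30))
  expect_equal(s75$harmonics, c(7.5, 15, 22.5, 30))
  expect_true(all(s6$z > 2.32))
  # brute-force check of the first z against the definitional formula
  hood <- noise_neighborhood()
  i <- round(6 * g$T) + 1
  idx <- oracle_noise_bins(g$amps[, 1], i)
  z_oracle <- (g$amps[i, 1] - mean(g$amps[idx, 1])) / sd(g$amps[idx, 1])
  expect_equal(s6$z[1], z_oracle, tolerance = 1e-12)
})

test_that("selection stops exactly where injected harmonics end", {
  g <- synthetic_grand(list(`6` = 1, `12` = 0.5, `7.5` = 0.8))
  expect_equal(select_harmonics_group(g, 6)$harmonics, c(6, 12))
  expect_equal(select_harmonics_group(g, 7.5)$harmonics, 7.5)
  # pure noise: empty set with a warning
  g0 <- synthetic_grand(list(), seed = 202)
  expect_warning(s0 <- select_harmonics_group(g0, 6), "not significant")
  expect_length(s0$harmonics, 0)
})

test_that("equalize-and-exclude removes shared harmonics and equalizes counts", {
  mk <- function(rate, h) structure(
    list(rate = rate, harmonics = h, z = seq_along(h) + 10,
         z_threshold = 2.32), class = "ft_harmonic_set")
  out <- equalize_and_exclude(mk(6, c(6, 12, 18, 24, 30)),
                              mk(7.5, c(7.5, 15, 22.5, 30)))
  expect_equal(out$a$harmonics, c(6, 12, 18))
  expect_equal(out$b$harmonics, c(7.5, 15, 22.5))
  expect_equal(out$a$n_retained, 3)
  # disjoint sets of equal length with no shared multiples: unchanged
  out2 <- equalize_and_exclude(mk(6, c(6, 12)), mk(7.5, c(7.5, 15)))
  expect_equal(out2$a$harmonics, c(6, 12))
  expect_equal(out2$b$harmonics, c(7.5, 15))
  # rates 4 and 10: shared harmonics are the multiples of lcm = 20
  lcm_brute <- min(intersect(4 * 1:50, 10 * 1:50))
  expect_equal(lcm_brute, 20)
  out3 <- equalize_and_exclude(mk(4, c(4, 8, 12, 16, 20)),
                               mk(10, c(10, 20, 30, 40)))
  expect_false(20 %in% out3$a$harmonics)
  expect_false(20 %in% out3$b$harmonics)
  expect_equal(length(out3$a$harmonics), length(out3$b$harmonics))
  expect_error(equalize_and_exclude(mk(6, 30), mk(7.5, 30)), "no harmonics")
})

test_that("harmonic summation is exact on noiseless spectra and commutes", {
  d <- tiny_design(); m <- roi_montage()
  s <- flat_subject(c(1, 0.5, 0.25), c(1, 0.5, 0.25), noise = 0, seed = 6)
  out <- simulate_subject_eeg(s, d, m, fs = 256)
  sp <- spectra_of(out$recording, d)[[1]]
  hood <- noise_neighborhood(side_width = 5)
  hs <- canonical_hsets()
  lot <- roi_definitions()$LOT
  got <- sum_harmonics(sp, hs[["6"]], lot, hood)
  expect_equal(got, 1.75, tolerance = 0.02)          # filter droop < 2%
  # ROI-average-then-sum equals sum-then-average
  bc <- baseline_corrected(sp, hs[["6"]]$harmonics, hood)$values
  per_electrode_sums <- rowSums(bc[match(lot, rownames(bc)), ])
  expect_equal(mean(per_electrode_sums), got, tolerance = 1e-12)
  # all-zero spectra sum to zero
  sp0 <- sp; sp0$amps[] <- 0
  expect_equal(sum_harmonics(sp0, hs[["6"]], lot, hood), 0)
  expect_error(sum_harmonics(sp, hs[["6"]], c("Oz", "QQ7"), hood), "missing")
})

test_that("summation is additive across superposed noiseless signals", {
  d <- tiny_design(); m <- roi_montage()
  hood <- noise_neighborhood(side_width = 5)
  hs <- canonical_hsets()
  lot <- roi_definitions()$LOT
  s1 <- flat_subject(c(0.6, 0.3, 0.15), noise = 0, seed = 21)
  s2 <- flat_subject(c(0.4, 0.2, 0.10), noise = 0, seed = 21)
  r1 <- simulate_subject_eeg(s1, d, m, fs = 256)$recording
  r2 <- simulate_subject_eeg(s2, d, m, fs = 256)$recording
  r12 <- r1; r12$samples <- r1$samples + r2$samples
  v <- vapply(list(r1, r2, r12), function(r)
    sum_harmonics(spectra_of(r, d)[[1]], hs[["6"]], lot, hood), 0)
  expect_equal(v[3], v[1] + v[2], tolerance = 1e-9)
})

test_that("individual significance applies the strict z > 1.64 rule", {
  # craft a spectrum whose summed mini-segment sits exactly at the threshold
  T <- 10; fs <- 40; n <- T * fs
  half <- floor(n / 2) + 1
  a <- rep(c(0.9, 1.1), length.out = half)
  mk <- function(centre_val) {
    a2 <- a; i <- round(6 * T) + 1; a2[i] <- centre_val
    structure(list(freqs = (seq_len(half) - 1) / T,
                   amps = matrix(a2, ncol = 1), T = T, n_samples = n, fs = fs,
                   labels = "Oz"), class = "ft_spectrum")
  }
  hset <- structure(list(rate = 6, harmonics = 6, z = 10, z_threshold = 2.32),
                    class = "ft_harmonic_set")
  hood <- noise_neighborhood(side_width = 20)
  i <- round(6 * T) + 1
  st <- fpvstag:::noise_stats_vec(a, i, hood)
  at_thr <- individual_significance(mk(st$mean + (1.64 - 1e-9) * st$sd),
                                    hset, "Oz")
  expect_equal(at_thr$z, 1.64, tolerance = 1e-6)
  expect_false(at_thr$significant)                  # strict inequality
  above <- individual_significance(mk(st$mean + 1.7 * st$sd), hset, "Oz")
  expect_true(above$significant)
})

test_that("individual significance is calibrated on noise and hits on signal", {
  set.seed(23)
  hset3 <- structure(list(rate = 6, harmonics = c(6, 12, 18), z = rep(10, 3),
                          z_threshold = 2.32), class = "ft_harmonic_set")
  T <- 10; fs <- 60; n <- T * fs; half <- floor(n / 2) + 1
  mk <- function(a) structure(
    list(freqs = (seq_len(half) - 1) / T, amps = matrix(a, ncol = 1),
         T = T, n_samples = n, fs = fs, labels = "Oz"),
    class = "ft_spectrum")
  # pure Rayleigh noise: false-positive rate within [0.02, 0.10]
  fp <- mean(replicate(500, {
    individual_significance(mk(sqrt(rnorm(half)^2 + rnorm(half)^2)),
                            hset3, "Oz")$significant
  }))
  expect_gte(fp, 0.02); expect_lte(fp, 0.10)
  # strong injected signal: always significant
  hits <- replicate(50, {
    a <- 0.1 * sqrt(rnorm(half)^2 + rnorm(half)^2)
    a[round(c(6, 12, 18) * T) + 1] <- a[round(c(6, 12, 18) * T) + 1] + c(1, 0.5, 0.25)
    individual_significance(mk(a), hset3, "Oz")$significant
  })
  expect_true(all(hits))
})
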