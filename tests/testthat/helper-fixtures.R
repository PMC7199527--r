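# Shared fixtures: small designs, reduced montages and subject builders used
# across the test files. Everything is generated in code.

# Short design for unit tests: 2 sequences, 6 s plateau, 1 s fades, 2 s gaps.
tiny_design <- function(n_sequences = 2, plateau = 6, fade = 1, gap = 5) {
  make_design(6, 7.5, n_sequences, full_contrast_duration = plateau,
              fade_duration = fade, inter_sequence_gap = gap)
}

# ROI electrodes plus Fpz (topography counterweight anchor / blink focus).
roi_montage <- function(extra = character(0)) {
  biosemi_montage(unique(c(unlist(roi_definitions()), "Fpz", extra)))
}

# Subject with uniform per-zone harmonic amplitude vectors.
flat_subject <- function(amps_face, amps_house = amps_face, noise = 0,
                         blink_rate = 0, seed = 1, group = "TD") {
  zones <- c("MO", "LOT", "ROT")
  subject_spec("t", group, 50,
               face_harmonic_amps = setNames(rep(list(amps_face), 3), zones),
               house_harmonic_amps = setNames(rep(list(amps_house), 3), zones),
               noise_scale = noise, blink_rate = blink_rate, seed = seed)
}

# Straight-line pipeline from a recording to per-condition spectra.
spectra_of <- function(rec, design, target_fs = 256, high = 100) {
  segs <- preprocess(rec, design, target_fs = target_fs, high = high)
  avg <- average_condition(crop_integer_cycles(segs))
  sps <- lapply(avg$segments, function(m)
    fft_amplitude(m, avg$fs, labels = avg$montage$label))
  names(sps) <- avg$labels
  sps
}

# Independent brute-force oracle for the retained noise bins: enumerate the
# full neighbourhood, drop adjacencies, then drop extremes one at a time
# (max first, ties at the lower frequency).
oracle_noise_bins <- function(a, i, side_width = 12, n_adjacent = 2,
                              n_extreme = 2) {
  idx <- setdiff((i - side_width):(i + side_width), i)
  half_adj <- n_adjacent / 2
  if (half_adj > 0)
    idx <- setdiff(idx, c((i - half_adj):(i - 1), (i + 1):(i + half_adj)))
  n_hi <- ceiling(n_extreme / 2); n_lo <- n_extreme - n_hi
  for (d in seq_len(n_hi)) {
    mx <- max(a[idx]); idx <- setdiff(idx, min(idx[a[idx] == mx]))
  }
  for (d in seq_len(n_lo)) {
    mn <- min(a[idx]); idx <- setdiff(idx, min(idx[a[idx] == mn]))
  }
  idx
}

# Direct O(N^2) DFT amplitude oracle (one-sided, 2/N scaling).
oracle_dft_amplitude <- function(x) {
  n <- length(x)
  half <- floor(n / 2) + 1
  amps <- vapply(0:(half - 1), function(k)
    Mod(sum(x * exp(-2i * pi * k * (0:(n - 1)) / n))) / n, 0)
  scale2 <- rep(2, half); scale2[1] <- 1
  if (n %% 2 == 0) scale2[half] <- 1
  amps * scale2
}

# Canonical retained harmonic sets for the 6 / 7.5 Hz design.
canonical_hsets <- function() {
  mk <- function(rate, h) structure(
    list(rate = rate, harmonics = h, z = rep(Inf, length(h)),
         z_threshold = 2.32, n_retained = length(h)),
    class = "ft_harmonic_set")
  list("6" = mk(6, c(6, 12, 18)), "7.5" = mk(7.5, c(7.5, 15, 22.5)))
}
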