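# Frequency-domain analysis: integer-cycle cropping, per-condition averaging,
# FFT amplitude spectra, and the three local-noise statistics (SNR,
# baseline-corrected amplitude, z-score).

#' Crop segments to an integer number of base-frequency cycles
#'
#' Starting at the first sample after fade-in, keeps the largest whole number
#' of base-frequency cycles whose duration is also a whole number of samples
#' and which fits inside the full-contrast plateau. After this crop both
#' stimulation rates fall exactly on FFT bin centres. With the default design
#' (60 s plateau, 1.5 Hz base) at 256 Hz the whole-sample cycle block is 3
#' cycles = 2 s = 512 samples, so the crop is 60 s = 15360 samples and the
#' spectral resolution is 1/60 Hz (approximately 0.017 Hz).
#'
#' @param segs An `ft_segments` (or per-condition average) carrying its design.
#' @param base_frequency Base rate in Hz (default: the design's largest common
#'   divisor of the two stimulation rates).
#' @param max_duration Optional cap in seconds on the cropped duration
#'   (default: the full-contrast plateau); used by the time-course analysis.
#' @return The cropped object, with attribute fields `crop_duration` (s)
#'   updated in `window`.
#' @export
crop_integer_cycles <- function(segs, base_frequency = NULL,
                                max_duration = NULL) {
  stopifnot(inherits(segs, "ft_segments"))
  d <- segs$design
  if (is.null(base_frequency)) base_frequency <- d$base_frequency
  fs <- segs$fs
  # smallest number of cycles c such that c * fs / base is a whole number
  samp_per_cycle <- fs / base_frequency
  c_block <- 1
  while (abs(c_block * samp_per_cycle - round(c_block * samp_per_cycle)) > 1e-9) {
    c_block <- c_block + 1
    if (c_block > 10000)
      ft_stop("no whole-cycle/whole-sample block for base %g Hz at %g Hz",
              "ft_crop_error", base_frequency, fs)
  }
  block_samp <- round(c_block * samp_per_cycle)
  avail <- d$full_contrast_duration
  if (!is.null(max_duration)) avail <- min(avail, max_duration)
  n_blocks <- floor(avail * fs / block_samp)
  if (n_blocks < 1)
    ft_stop("available plateau (%g s) shorter than one whole-sample cycle block (%g s)",
            "ft_crop_error", avail, block_samp / fs)
  n_keep <- n_blocks * block_samp
  # window is plateau-anchored: plateau (= first sample after fade-in) starts
  # at -window[1] seconds into the segment
  start <- round(-segs$window[1] * fs) + 1
  segs$segments <- lapply(segs$segments, function(m)
    m[start + 0:(n_keep - 1), , drop = FALSE])
  segs$window <- c(0, n_keep / fs)
  segs$steps <- c(segs$steps, "crop")
  segs
}

#' Average segments per condition in the time domain
#'
#' Segments sharing a condition label (same category-to-rate mapping) are
#' averaged element-wise, preserving the stimulation-locked phase while
#' reducing out-of-phase background activity by about `1/sqrt(n)`.
#'
#' @param segs An `ft_segments`.
#' @return An `ft_segments` with one segment per condition (labels become the
#'   unique condition labels, in order of first appearance).
#' @export
average_condition <- function(segs) {
  stopifnot(inherits(segs, "ft_segments"))
  lens <- vapply(segs$segments, nrow, 0L)
  if (length(unique(lens)) != 1)
    ft_stop("segments have unequal lengths", "ft_shape_error")
  conds <- unique(segs$labels)
  avg <- lapply(conds, function(cond) {
    ms <- segs$segments[segs$labels == cond]
    Reduce(`+`, ms) / length(ms)
  })
  segs$segments <- avg
  segs$labels <- conds
  segs$steps <- c(segs$steps, "average")
  segs
}

#' One-sided FFT amplitude spectrum
#'
#' Transforms a (cropped, averaged) segment to a one-sided amplitude spectrum
#' scaled so that a pure sinusoid of amplitude A at a bin frequency reads A
#' (2/N scaling, DC and Nyquist unscaled by 2). Amplitudes are in the input's
#' units (microvolts).
#'
#' @param x Numeric matrix (time x channels) or vector.
#' @param fs Sampling rate in Hz.
#' @param labels Optional channel labels.
#' @return An object of class `ft_spectrum`: list with `freqs` (Hz, from 0 at
#'   spacing `fs/N`), `amps` (bins x channels matrix), `T` (analyzed duration
#'   in s), `n_samples`, `fs`, `labels`.
#' @export
fft_amplitude <- function(x, fs, labels = NULL) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  if (n < 2) ft_stop("input too short for a spectrum", "ft_shape_error")
  X <- stats::mvfft(x)
  half <- floor(n / 2) + 1
  amps <- abs(X[seq_len(half), , drop = FALSE]) / n
  scale2 <- rep(2, half); scale2[1] <- 1
  if (n %% 2 == 0) scale2[half] <- 1
  amps <- amps * scale2
  if (is.null(labels)) labels <- colnames(x)
  structure(list(freqs = (seq_len(half) - 1) * fs / n, amps = amps,
                 T = n / fs, n_samples = n, fs = fs, labels = labels),
            class = "ft_spectrum")
}

#' @export
print.ft_spectrum <- function(x, ...) {
  cat(sprintf("ft_spectrum: %d bins x %d channels, df = %.5f Hz (T = %.2f s)\n",
              length(x$freqs), ncol(x$amps), x$fs / x$n_samples, x$T))
  invisible(x)
}

#' Locate the FFT bin of a target frequency
#'
#' Target frequencies are required to fall on exact bin centres (within
#' `df/100`); a larger mismatch raises an error rather than snapping silently.
#'
#' @param spec An `ft_spectrum`.
#' @param freq Target frequency in Hz.
#' @return Integer bin index (1-based).
#' @export
bin_at <- function(spec, freq) {
  df <- spec$fs / spec$n_samples
  i <- round(freq / df) + 1
  if (i < 1 || i > length(spec$freqs))
    ft_stop("frequency %g Hz outside spectrum", "ft_grid_error", freq)
  if (abs(spec$freqs[i] - freq) > df / 100)
    ft_stop("frequency %g Hz misses the bin grid by %.3g Hz (> df/100)",
            "ft_grid_error", freq, abs(spec$freqs[i] - freq))
  i
}

#' Define a local noise neighbourhood
#'
#' The noise estimate at a target bin uses `side_width` bins on each side,
#' excluding the bins directly adjacent to the target (`n_adjacent` in total,
#' half per side) and the `n_extreme` bins with the most extreme amplitudes
#' among the remainder (half maxima, half minima; ties resolved toward lower
#' frequency). Defaults (12/2/2) retain 20 noise bins.
#'
#' @param side_width Bins per side (default 12).
#' @param n_adjacent Total adjacent bins excluded (default 2; must be even).
#' @param n_extreme Total extreme bins excluded (default 2).
#' @return An object of class `ft_neighborhood` with the retained-bin count in
#'   `n_bins`.
#' @export
noise_neighborhood <- function(side_width = 12, n_adjacent = 2, n_extreme = 2) {
  if (n_adjacent %% 2 != 0)
    ft_stop("n_adjacent must be even (half per side)", "ft_neighborhood_error")
  n_bins <- 2 * side_width - n_adjacent - n_extreme
  if (n_bins < 2)
    ft_stop("neighbourhood retains fewer than 2 bins", "ft_neighborhood_error")
  structure(list(side_width = side_width, n_adjacent = n_adjacent,
                 n_extreme = n_extreme, n_bins = n_bins),
            class = "ft_neighborhood")
}

# Retained neighbour offsets/indices and noise statistics for one target
# index of an amplitude vector. Returns mean and sample SD over the retained
# bins, plus the retained indices (used by the brute-force oracle tests).
noise_stats_vec <- function(a, i, hood) {
  sw <- hood$side_width
  if (i - sw < 1 || i + sw > length(a))
    ft_stop("target bin %d too close to spectrum edge for side width %d",
            "ft_neighborhood_error", i, sw)
  offs <- c(-(sw:1), 1:sw)
  adj <- hood$n_adjacent / 2
  if (adj > 0) offs <- offs[abs(offs) > adj]
  idx <- i + offs
  vals <- a[idx]
  n_hi <- ceiling(hood$n_extreme / 2)
  n_lo <- hood$n_extreme - n_hi
  drop <- integer(0)
  if (n_hi > 0) {
    ord <- order(-vals, idx)          # largest first; tie -> lower frequency
    drop <- c(drop, ord[seq_len(n_hi)])
  }
  if (n_lo > 0) {
    ord <- order(vals, idx)           # smallest first; tie -> lower frequency
    ord <- setdiff(ord, drop)
    drop <- c(drop, ord[seq_len(n_lo)])
  }
  keep <- setdiff(seq_along(idx), drop)
  r <- vals[keep]
  list(mean = mean(r), sd = stats::sd(r), indices = idx[keep])
}

#' Local noise estimate around a target frequency
#'
#' Mean and SD of the amplitudes over the retained noise bins of the
#' neighbourhood (20 bins by default), per channel.
#'
#' @param spec An `ft_spectrum`.
#' @param freq Target frequency in Hz (must be a bin centre).
#' @param hood An [noise_neighborhood()].
#' @return List with numeric vectors `mean` and `sd` (one entry per channel).
#' @export
local_noise <- function(spec, freq, hood = noise_neighborhood()) {
  i <- bin_at(spec, freq)
  st <- apply(spec$amps, 2, function(a) {
    s <- noise_stats_vec(a, i, hood); c(s$mean, s$sd)
  })
  list(mean = st[1, ], sd = st[2, ])
}

spectral_stat <- function(spec, freqs, hood, fun, kind) {
  vals <- vapply(freqs, function(f) {
    i <- bin_at(spec, f)
    vapply(seq_len(ncol(spec$amps)), function(ch) {
      a <- spec$amps[, ch]
      s <- noise_stats_vec(a, i, hood)
      fun(a[i], s$mean, s$sd)
    }, 0)
  }, numeric(ncol(spec$amps)))
  vals <- matrix(vals, nrow = ncol(spec$amps),
                 dimnames = list(spec$labels, sprintf("%g", freqs)))
  structure(list(kind = kind, freqs = freqs, values = vals,
                 neighborhood = hood), class = "ft_spectral_stat")
}

#' Signal-to-noise ratio at target frequencies
#'
#' SNR = amplitude divided by the local-noise mean, per channel and target
#' frequency.
#'
#' @param spec An `ft_spectrum`.
#' @param freqs Target frequencies in Hz.
#' @param hood An [noise_neighborhood()].
#' @return An `ft_spectral_stat` (values: channels x frequencies).
#' @export
snr_spectrum <- function(spec, freqs, hood = noise_neighborhood()) {
  spectral_stat(spec, freqs, hood, function(a, m, s) {
    if (m <= 0) ft_stop("noise mean is zero; SNR undefined", "ft_snr_error")
    a / m
  }, "SNR")
}

#' Baseline-corrected amplitude at target frequencies
#'
#' Amplitude minus the local-noise mean, in microvolts (may be negative).
#'
#' @inheritParams snr_spectrum
#' @return An `ft_spectral_stat`.
#' @export
baseline_corrected <- function(spec, freqs, hood = noise_neighborhood()) {
  spectral_stat(spec, freqs, hood, function(a, m, s) a - m, "baseline_corrected")
}

#' Z-score at target frequencies
#'
#' (amplitude - local-noise mean) / local-noise SD.
#'
#' @inheritParams snr_spectrum
#' @return An `ft_spectral_stat`.
#' @export
zscore_spectrum <- function(spec, freqs, hood = noise_neighborhood()) {
  spectral_stat(spec, freqs, hood, function(a, m, s) {
    if (s <= 0) ft_stop("noise SD is zero; z-score undefined", "ft_zscore_error")
    (a - m) / s
  }, "zscore")
}

#' Export a spectrum and its statistics as a long table
#'
#' @param spec An `ft_spectrum`.
#' @param freqs Target frequencies at which to evaluate the statistics.
#' @param hood An [noise_neighborhood()].
#' @return data.frame with columns `freq`, `channel`, `amplitude`, `snr`,
#'   `baseline_corrected`, `zscore`.
#' @export
spectrum_table <- function(spec, freqs, hood = noise_neighborhood()) {
  snr <- snr_spectrum(spec, freqs, hood)$values
  bc <- baseline_corrected(spec, freqs, hood)$values
  z <- zscore_spectrum(spec, freqs, hood)$values
  labels <- if (is.null(spec$labels)) sprintf("ch%d", seq_len(ncol(spec$amps))) else spec$labels
  out <- expand.grid(channel = labels, freq = freqs, stringsAsFactors = FALSE)
  bins <- vapply(freqs, function(f) as.integer(bin_at(spec, f)), 0L)
  out$amplitude <- spec$amps[cbind(bins[match(out$freq, freqs)],
                                   match(out$channel, labels))]
  out$snr <- snr[cbind(match(out$channel, labels), match(out$freq, freqs))]
  out$baseline_corrected <- bc[cbind(match(out$channel, labels), match(out$freq, freqs))]
  out$zscore <- z[cbind(match(out$channel, labels), match(out$freq, freqs))]
  out[, c("freq", "channel", "amplitude", "snr", "baseline_corrected", "zscore")]
}
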