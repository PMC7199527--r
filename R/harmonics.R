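# Harmonic selection, ROI harmonic summation, and individual-subject
# significance -- the quantification core of the pipeline.

roi_average <- function(spec, electrodes) {
  i <- match(electrodes, spec$labels)
  if (anyNA(i))
    ft_stop("ROI electrode(s) missing from spectrum: %s", "ft_montage_error",
            paste(electrodes[is.na(i)], collapse = ", "))
  rowMeans(spec$amps[, i, drop = FALSE])
}

# Build an ft_spectrum holding a single (ROI-averaged or grand-averaged)
# amplitude vector on the same grid as `like`.
spectrum_like <- function(amps, like, label = "avg") {
  out <- like
  out$amps <- matrix(amps, ncol = 1)
  out$labels <- label
  out
}

#' Select response harmonics from group-level z-score spectra
#'
#' Walks the harmonics k = 1, 2, ... of a stimulation rate and retains the
#' consecutive run whose group-level z-score exceeds the threshold, stopping
#' at the first non-significant harmonic. The z-scores are computed on the
#' supplied grand-averaged amplitude spectrum (averaged across subjects and
#' ROI electrodes), using the local-noise neighbourhood.
#'
#' @param grand_spec An `ft_spectrum` with a single column: the grand-averaged
#'   amplitude spectrum.
#' @param rate Stimulation rate in Hz.
#' @param z_threshold Significance threshold (default 2.32, one-tailed
#'   p < 0.01); strict inequality.
#' @param hood An [noise_neighborhood()].
#' @param max_freq Highest harmonic frequency considered (default 100 Hz,
#'   bounded by the spectrum's evaluable range).
#' @return An object of class `ft_harmonic_set`: `rate`, `harmonics`
#'   (frequencies retained, strictly increasing), `z` (their z-scores),
#'   `z_threshold`. Warns and returns an empty set if the fundamental itself
#'   is not significant.
#' @export
select_harmonics_group <- function(grand_spec, rate, z_threshold = 2.32,
                                   hood = noise_neighborhood(),
                                   max_freq = 100) {
  stopifnot(inherits(grand_spec, "ft_spectrum"))
  if (ncol(grand_spec$amps) != 1)
    ft_stop("grand_spec must have a single grand-averaged column",
            "ft_shape_error")
  df <- grand_spec$fs / grand_spec$n_samples
  top <- min(max_freq, max(grand_spec$freqs) - hood$side_width * df)
  harmonics <- numeric(0); zs <- numeric(0)
  k <- 1
  while (k * rate <= top) {
    z <- zscore_spectrum(grand_spec, k * rate, hood)$values[1, 1]
    if (z > z_threshold) {
      harmonics <- c(harmonics, k * rate); zs <- c(zs, z)
    } else break
    k <- k + 1
  }
  if (length(harmonics) == 0)
    warning(sprintf("fundamental %g Hz not significant at z > %g; empty harmonic set",
                    rate, z_threshold))
  structure(list(rate = rate, harmonics = harmonics, z = zs,
                 z_threshold = z_threshold), class = "ft_harmonic_set")
}

#' @export
print.ft_harmonic_set <- function(x, ...) {
  cat(sprintf("Harmonics of %g Hz (z > %g): %s\n", x$rate, x$z_threshold,
              if (length(x$harmonics)) paste(x$harmonics, collapse = ", ")
              else "(none)"))
  invisible(x)
}

#' Canonical harmonic sets for a design, by rule
#'
#' Builds, without looking at data, the harmonic sets the selection procedure
#' converges to when all injected harmonics are strong: the first `n`
#' harmonics of each rate that are not shared between the two rates (for 6
#' and 7.5 Hz: 6, 12, 18 and 7.5, 15, 22.5; the shared 30 Hz is skipped).
#' Useful when the quantification is run standalone, e.g. in recovery
#' experiments.
#'
#' @param design An `ft_design`.
#' @param n Harmonics per rate (default 3).
#' @return Named list of two `ft_harmonic_set`s (names are the rates).
#' @export
default_harmonic_sets <- function(design, n = 3) {
  rates <- sort(unique(c(design$f_face, design$f_house)))
  out <- lapply(seq_along(rates), function(i) {
    r <- rates[i]; other <- rates[-i]
    h <- r * seq_len(4 * n)
    h <- h[!vapply(h, function(f) any(is_multiple_of(f, other)), TRUE)]
    structure(list(rate = r, harmonics = h[seq_len(n)],
                   z = rep(NA_real_, n), z_threshold = 2.32, n_retained = n),
              class = "ft_harmonic_set")
  })
  names(out) <- sprintf("%g", rates)
  out
}

#' Equalize harmonic counts and exclude shared harmonics
#'
#' Removes from both sets any frequency that is an integer multiple of both
#' stimulation rates (e.g. 30 Hz for 6 and 7.5 Hz), then truncates both sets
#' to the shorter length so each rate contributes the same number of
#' harmonics. Order is preserved.
#'
#' @param set_a,set_b `ft_harmonic_set`s for the two rates of one design.
#' @return List of the two pruned `ft_harmonic_set`s (named `a` and `b`).
#' @export
equalize_and_exclude <- function(set_a, set_b) {
  stopifnot(inherits(set_a, "ft_harmonic_set"), inherits(set_b, "ft_harmonic_set"))
  shared <- function(f) is_multiple_of(f, set_a$rate) & is_multiple_of(f, set_b$rate)
  prune <- function(s) {
    keep <- !shared(s$harmonics)
    s$harmonics <- s$harmonics[keep]; s$z <- s$z[keep]; s
  }
  a <- prune(set_a); b <- prune(set_b)
  n <- min(length(a$harmonics), length(b$harmonics))
  if (n == 0)
    ft_stop("no harmonics left after shared-harmonic exclusion",
            "ft_quantification_error")
  trim <- function(s) {
    s$harmonics <- s$harmonics[seq_len(n)]; s$z <- s$z[seq_len(n)]
    s$n_retained <- n; s
  }
  list(a = trim(a), b = trim(b))
}

#' Sum baseline-corrected amplitudes over harmonics within an ROI
#'
#' Baseline-corrected values are averaged across the ROI electrodes and summed
#' over the retained harmonics. Averaging and summing commute (both are
#' linear); the ROI-average-then-sum order is used.
#'
#' @param spec An `ft_spectrum` of raw amplitudes (per electrode).
#' @param hset An `ft_harmonic_set`.
#' @param roi Character vector of ROI electrode labels.
#' @param hood An [noise_neighborhood()].
#' @return Numeric scalar: summed baseline-corrected amplitude in microvolts.
#' @export
sum_harmonics <- function(spec, hset, roi, hood = noise_neighborhood()) {
  if (length(hset$harmonics) == 0)
    ft_stop("empty harmonic set", "ft_quantification_error")
  bc <- baseline_corrected(spec, hset$harmonics, hood)$values
  i <- match(roi, rownames(bc))
  if (anyNA(i))
    ft_stop("ROI electrode(s) missing: %s", "ft_montage_error",
            paste(roi[is.na(i)], collapse = ", "))
  sum(colMeans(bc[i, , drop = FALSE]))
}

#' Individual-subject significance of a summed harmonic response
#'
#' Implements the four-step procedure: (1) the raw amplitude spectrum is
#' averaged across the ROI electrodes; (2) mini-spectra centred on each
#' retained harmonic, extending `extract_side` bins per side, are extracted;
#' (3) the mini-spectra are summed element-wise across harmonics; (4) the
#' centre bin of the summed mini-spectrum is z-scored against its surrounding
#' bins, applying the standard exclusion convention (adjacent and extreme bins
#' dropped). The response is significant if z exceeds the threshold
#' (strictly).
#'
#' @param spec An `ft_spectrum` of raw amplitudes (per electrode).
#' @param hset An `ft_harmonic_set`.
#' @param roi Character vector of ROI electrode labels.
#' @param extract_side Bins per side of each extracted mini-spectrum
#'   (default 20).
#' @param hood Exclusion convention applied when z-scoring the summed
#'   mini-spectrum; its `side_width` is set to `extract_side` (defaults keep
#'   2 adjacent + 2 extreme bins excluded, i.e. 36 noise bins).
#' @param z_threshold Significance threshold (default 1.64, one-tailed
#'   p < 0.05); strict inequality.
#' @return List with `z`, `significant`, `summed_segment` (the summed
#'   mini-spectrum) and `z_threshold`.
#' @export
individual_significance <- function(spec, hset, roi, extract_side = 20,
                                    hood = noise_neighborhood(
                                      side_width = extract_side),
                                    z_threshold = 1.64) {
  if (length(hset$harmonics) == 0)
    ft_stop("empty harmonic set", "ft_quantification_error")
  avg <- roi_average(spec, roi)
  centre <- extract_side + 1
  segs <- lapply(hset$harmonics, function(f) {
    i <- bin_at(spec, f)
    if (i - extract_side < 1 || i + extract_side > length(avg))
      ft_stop("harmonic %g Hz too close to spectrum edge", "ft_neighborhood_error", f)
    avg[(i - extract_side):(i + extract_side)]
  })
  summed <- Reduce(`+`, segs)
  st <- noise_stats_vec(summed, centre, hood)
  if (st$sd <= 0)
    ft_stop("noise SD is zero; z-score undefined", "ft_zscore_error")
  z <- (summed[centre] - st$mean) / st$sd
  list(z = z, significant = z > z_threshold, summed_segment = summed,
       z_threshold = z_threshold)
}
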