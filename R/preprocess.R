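# Sequence-locked preprocessing: segmentation, zero-phase Butterworth
# band-pass, resampling, bad-channel interpolation, common average reference.
# The canonical order is segment -> filter -> resample -> interpolate ->
# re-reference; each step stamps a provenance flag on the segment set so the
# order can be asserted downstream.

new_segments <- function(segments, labels, fs, montage, window, design,
                         steps = character(0)) {
  structure(list(segments = segments, labels = labels, fs = fs,
                 montage = montage, window = window, design = design,
                 steps = steps), class = "ft_segments")
}

#' @export
print.ft_segments <- function(x, ...) {
  cat(sprintf("ft_segments: %d segments x %d channels x %d samples @ %g Hz\n",
              length(x$segments), ncol(x$segments[[1]]),
              nrow(x$segments[[1]]), x$fs))
  cat(sprintf("  window [%g, %g] s, steps: %s\n", x$window[1], x$window[2],
              if (length(x$steps)) paste(x$steps, collapse = " > ") else "none"))
  invisible(x)
}

add_step <- function(segs, step) { segs$steps <- c(segs$steps, step); segs }

#' Cut a continuous recording into sequence-locked segments
#'
#' Extracts one segment per sequence-onset event. The window is anchored to
#' the full-contrast plateau: each segment spans `pre` seconds before the end
#' of fade-in to `post` seconds after the end of the plateau, so the default
#' 2 s + 60 s + 5 s = 67 s segment starts exactly at the sequence onset (the
#' 2 s fade-in fills the pre-window) and ends 5 s after full-contrast
#' stimulation stops. The condition label is taken from the event marker.
#'
#' @param rec An `ft_recording` whose events mark sequence onsets (fade-in
#'   start).
#' @param design The `ft_design` used (provides plateau and fade timing).
#' @param pre Seconds before the full-contrast plateau (default 2).
#' @param post Seconds after the plateau (default 5).
#' @return An `ft_segments` object; window is `[-pre, plateau + post]`
#'   relative to plateau start.
#' @export
segment_sequences <- function(rec, design, pre = 2, post = 5) {
  stopifnot(inherits(rec, "ft_recording"), inherits(design, "ft_design"))
  if (nrow(rec$events) == 0)
    ft_stop("recording has no sequence-onset events", "ft_metadata_error")
  if (any(is.na(rec$events$label) | rec$events$label == ""))
    ft_stop("unlabeled sequence-onset event", "ft_metadata_error")
  plateau <- design$full_contrast_duration
  fade <- design$fade_duration
  n <- nrow(rec$samples)
  seg_len <- round((pre + plateau + post) * rec$fs)
  segs <- vector("list", nrow(rec$events))
  for (i in seq_len(nrow(rec$events))) {
    t0 <- rec$events$time[i] + fade - pre
    start <- round(t0 * rec$fs) + 1
    if (start < 1 || start + seg_len - 1 > n)
      ft_stop("segment %d [%g, %g] s exceeds recording bounds",
              "ft_truncation_error", i, t0, t0 + pre + plateau + post)
    segs[[i]] <- rec$samples[start + 0:(seg_len - 1), , drop = FALSE]
  }
  new_segments(segs, rec$events$label, rec$fs, rec$montage,
               c(-pre, plateau + post), design, steps = "segment")
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass of the given order forward and backward
#' (zero-phase, so stimulation-locked phase is preserved) to every channel of
#' every segment.
#'
#' @param segs An `ft_segments`.
#' @param low,high Band edges in Hz (defaults 0.1 and 100).
#' @param order Butterworth design order (default 4).
#' @return Filtered `ft_segments`.
#' @export
bandpass_segments <- function(segs, low = 0.1, high = 100, order = 4) {
  stopifnot(inherits(segs, "ft_segments"))
  nyq <- segs$fs / 2
  if (low <= 0 || low >= high)
    ft_stop("need 0 < low < high (got %g, %g)", "ft_filter_error", low, high)
  if (high >= nyq)
    ft_stop("high edge %g Hz must be below Nyquist (%g Hz)",
            "ft_filter_error", high, nyq)
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  segs$segments <- lapply(segs$segments, function(m) {
    apply(m, 2, function(col) signal::filtfilt(bf, col))
  })
  add_step(segs, "bandpass")
}

#' Downsample segments
#'
#' For integer decimation ratios (e.g. 512 to 256 Hz) every k-th sample is
#' kept; anti-aliasing is provided by the preceding band-pass (100 Hz low-pass
#' is well below the new Nyquist). Non-integer ratios use polyphase
#' resampling via [signal::resample()].
#'
#' @param segs An `ft_segments`.
#' @param target_fs Target sampling rate in Hz (default 256); must not exceed
#'   the current rate.
#' @return Resampled `ft_segments`.
#' @export
resample_segments <- function(segs, target_fs = 256) {
  stopifnot(inherits(segs, "ft_segments"))
  if (target_fs > segs$fs)
    ft_stop("upsampling not supported (%g -> %g Hz)", "ft_resample_error",
            segs$fs, target_fs)
  if (target_fs == segs$fs) return(add_step(segs, "resample"))
  ratio <- segs$fs / target_fs
  if (abs(ratio - round(ratio)) < 1e-9) {
    k <- round(ratio)
    segs$segments <- lapply(segs$segments, function(m)
      m[seq(1, nrow(m), by = k), , drop = FALSE])
  } else {
    segs$segments <- lapply(segs$segments, function(m)
      apply(m, 2, function(col) signal::resample(col, target_fs, segs$fs)))
  }
  segs$fs <- target_fs
  add_step(segs, "resample")
}

#' Interpolate noisy channels from their three nearest neighbours
#'
#' Replaces each listed channel with the inverse-distance-weighted mean of its
#' three spatially nearest good electrodes (3-D unit-sphere distance). At most
#' 5% of channels may be interpolated.
#'
#' @param segs An `ft_segments`.
#' @param bad Character vector of channel labels to interpolate (may be empty).
#' @param n_neighbors Number of nearest good neighbours (default 3).
#' @return `ft_segments` with bad channels replaced.
#' @export
interpolate_bad_channels <- function(segs, bad, n_neighbors = 3) {
  stopifnot(inherits(segs, "ft_segments"))
  if (length(bad) == 0) return(add_step(segs, "interpolate"))
  labels <- segs$montage$label
  unknown <- setdiff(bad, labels)
  if (length(unknown))
    ft_stop("bad channel(s) not in montage: %s", "ft_montage_error",
            paste(unknown, collapse = ", "))
  limit <- floor(0.05 * length(labels))
  if (length(bad) > limit)
    ft_stop("%d bad channels exceed the 5%% limit (%d of %d)",
            "ft_too_many_bad_error", length(bad), limit, length(labels))
  P <- montage_positions(segs$montage)
  good <- setdiff(labels, bad)
  weights <- lapply(bad, function(b) {
    d <- sqrt(colSums((t(P[match(good, labels), , drop = FALSE]) -
                         P[match(b, labels), ])^2))
    nb <- good[order(d)[seq_len(n_neighbors)]]
    dn <- d[order(d)[seq_len(n_neighbors)]]
    if (any(dn < 1e-12)) dn <- pmax(dn, 1e-12)
    w <- (1 / dn) / sum(1 / dn)
    list(neighbors = match(nb, labels), w = w)
  })
  names(weights) <- bad
  segs$segments <- lapply(segs$segments, function(m) {
    for (b in bad) {
      wb <- weights[[b]]
      m[, match(b, labels)] <-
        m[, wb$neighbors, drop = FALSE] %*% wb$w
    }
    m
  })
  add_step(segs, "interpolate")
}

#' Re-reference to the common average
#'
#' Subtracts, at every sample, the instantaneous mean across all channels, so
#' the per-sample channel mean becomes zero. Idempotent.
#'
#' @param segs An `ft_segments` with at least two channels.
#' @return Re-referenced `ft_segments`.
#' @export
rereference_average <- function(segs) {
  stopifnot(inherits(segs, "ft_segments"))
  if (ncol(segs$segments[[1]]) < 2)
    ft_stop("common average reference undefined for a single channel",
            "ft_reference_error")
  segs$segments <- lapply(segs$segments, function(m) m - rowMeans(m))
  add_step(segs, "rereference")
}

#' Flag unusually noisy channels by variance threshold
#'
#' Optional helper (not part of the default chain, where bad channels are a
#' user-supplied list): flags channels whose log-variance, pooled over
#' segments, exceeds the across-channel median by more than `z` robust SDs
#' (MAD). Never returns more channels than the 5% interpolation limit allows.
#'
#' @param segs An `ft_segments`.
#' @param z Robust z threshold (default 4).
#' @return Character vector of flagged channel labels (possibly empty).
#' @export
detect_bad_channels <- function(segs, z = 4) {
  stopifnot(inherits(segs, "ft_segments"))
  v <- Reduce(`+`, lapply(segs$segments, function(m) apply(m, 2, stats::var)))
  lv <- log(v + 1e-12)
  dev <- (lv - stats::median(lv)) / max(stats::mad(lv), 1e-12)
  bad <- segs$montage$label[dev > z]
  limit <- floor(0.05 * length(lv))
  if (length(bad) > limit)
    bad <- bad[order(dev[segs$montage$label %in% bad],
                     decreasing = TRUE)][seq_len(limit)]
  bad
}

#' Run the full preprocessing chain
#'
#' Segment -> band-pass -> resample -> interpolate -> re-reference, in the
#' fixed canonical order, stamping provenance at each step.
#'
#' @param rec An `ft_recording`.
#' @param design The `ft_design` used during acquisition.
#' @param pre,post Segmentation window padding in seconds (defaults 2 and 5).
#' @param low,high,order Band-pass parameters (defaults 0.1 Hz, 100 Hz, 4).
#' @param target_fs Resampling target (default 256 Hz).
#' @param bad Channels to interpolate (default none).
#' @return A preprocessed `ft_segments`.
#' @export
preprocess <- function(rec, design, pre = 2, post = 5, low = 0.1, high = 100,
                       order = 4, target_fs = 256, bad = character(0)) {
  segs <- segment_sequences(rec, design, pre = pre, post = post)
  segs <- bandpass_segments(segs, low = low, high = high, order = order)
  segs <- resample_segments(segs, target_fs = target_fs)
  segs <- interpolate_bad_channels(segs, bad = bad)
  rereference_average(segs)
}
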