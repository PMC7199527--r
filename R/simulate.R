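# Synthetic steady-state EEG generation.

# Power-law (1/f^alpha) background noise with a relative white floor,
# generated by frequency-domain shaping of white Gaussian noise. The shaping
# weights are normalized to unit mean square, so each output channel has
# variance `scale^2` in expectation without per-realization rescaling (which
# would break independence across channels).
pink_noise <- function(n, n_channels, fs, scale = 15, alpha = 1,
                       floor_frac = 0.1, f_lo = 0.1) {
  m <- stats::nextn(n, c(2, 3, 5))          # FFT-friendly length, then truncate
  f <- (0:(m - 1)) * fs / m
  f <- pmin(f, fs - f)                      # two-sided frequency axis
  p <- (1 / pmax(f, f_lo))^alpha
  p <- p / max(p)
  p <- (1 - floor_frac) * p + floor_frac
  w <- sqrt(p)
  w[1] <- 0                                 # no DC
  w <- w / sqrt(mean(w^2))
  x <- matrix(rnorm(m * n_channels), m, n_channels)
  x <- Re(stats::mvfft(stats::mvfft(x) * w, inverse = TRUE)) / m
  x[seq_len(n), , drop = FALSE] * scale
}

#' Expected amplitude-spectrum noise floor of the background model
#'
#' Closed-form expectation of the local-noise amplitude per frequency bin for
#' the package's 1/f-plus-white-floor background: a Rayleigh bin amplitude
#' has mean `scale/sqrt(n_avg) * w(f) * sqrt(pi / n_samples)`, where `w` is
#' the mean-square-normalized spectral shaping weight and `n_avg` the number
#' of time-domain-averaged segments. Baseline correction subtracts exactly
#' this floor from a strong signal bin, so the quantity is also the expected
#' per-harmonic offset of baseline-corrected estimates (see the methods
#' vignette).
#'
#' @param freqs Frequencies in Hz.
#' @param noise_scale Background RMS per channel (microvolts).
#' @param alpha,floor_frac,f_lo Background shape (see [cohort_effects()]).
#' @param fs_band Acquisition sampling rate: the band over which the shaping
#'   weights are normalized, i.e. over which the total RMS is spread
#'   (default 512).
#' @param n_samples Analyzed (cropped) segment length in samples *at the
#'   acquisition rate* (default 30720 = 60 s at 512 Hz). Downsampling after
#'   an anti-alias low-pass preserves the spectral density below the new
#'   Nyquist, so the per-bin floor is set by the acquisition-rate duration.
#' @param n_avg Number of segments averaged per condition (default 2).
#' @return Numeric vector of expected floor amplitudes (microvolts per bin).
#' @export
expected_noise_floor <- function(freqs, noise_scale = 15, alpha = 1,
                                 floor_frac = 0.1, f_lo = 0.1, fs_band = 512,
                                 n_samples = 30720, n_avg = 2) {
  pfun <- function(f) {
    pr <- (f_lo / pmax(f, f_lo))^alpha
    (1 - floor_frac) * pr + floor_frac
  }
  grid <- seq(0, fs_band / 2, length.out = 8192)
  w <- sqrt(pfun(freqs) / mean(pfun(grid)))
  noise_scale / sqrt(n_avg) * w * sqrt(pi / n_samples)
}

# 400 ms biphasic blink transient, peak-normalized.
blink_template <- function(fs, duration = 0.4) {
  t <- seq(0, duration, by = 1 / fs)
  b <- sin(2 * pi * t / duration) * sin(pi * t / duration)
  b / max(abs(b))
}

# Per-channel injected amplitude for one category and harmonic, from per-zone
# amplitudes. Channels belonging to a zone receive exactly that zone's
# amplitude; other channels receive the largest Gaussian-decayed contribution
# of any zone (angular distance to the zone's nearest electrode, sd `sigma`
# radians). Parametric topography, not a volume-conduction model.
zone_channel_amps <- function(zone_amps_k, montage, zones, sigma = 0.3) {
  P <- montage_positions(montage)
  amp <- numeric(nrow(montage))
  decayed <- matrix(0, nrow(montage), length(zone_amps_k))
  for (zi in seq_along(zone_amps_k)) {
    zlabs <- zones[[names(zone_amps_k)[zi]]]
    Q <- montage_positions(montage, zlabs)
    d <- apply(Q, 1, function(q) angular_dist(P, q))
    dmin <- apply(d, 1, min)
    decayed[, zi] <- zone_amps_k[[zi]] * exp(-dmin^2 / (2 * sigma^2))
    amp[montage$label %in% zlabs] <- zone_amps_k[[zi]]  # exact inside the zone
  }
  out <- apply(decayed, 1, max)
  inroi <- montage$label %in% unlist(zones[names(zone_amps_k)])
  out[inroi] <- amp[inroi]
  out
}

# Balance a non-negative posterior topography with an opposite-phase frontal
# far field so the signed amplitude vector sums to zero across channels.
# Common average referencing then leaves every channel's injected amplitude
# untouched (real average-referenced topographies are likewise zero-mean and
# dipolar). The counterweight is a truncated Gaussian around Fpz that reaches
# exactly zero 1.5 rad away, so posterior ROI amplitudes are not perturbed at
# all.
center_topography <- function(amp, montage, sigma = 0.9, cutoff = 1.5) {
  if (all(amp == 0)) return(amp)
  P <- montage_positions(montage)
  anchor <- if ("Fpz" %in% montage$label) "Fpz" else
    montage$label[which.max(angular_dist(P, as.numeric(P[which.max(amp), ])))]
  d <- angular_dist(P, montage_positions(montage, anchor)[1, ])
  g <- as.numeric(pmax(0, exp(-d^2 / (2 * sigma^2)) -
                         exp(-cutoff^2 / (2 * sigma^2))))
  if (sum(g) <= 0) g <- as.numeric(d == min(d))
  amp - (sum(amp) / sum(g)) * g
}

#' Simulate one subject's frequency-tagging EEG recording
#'
#' Produces a continuous multichannel recording containing the design's
#' stimulation sequences separated by noise-only gaps. Within each sequence
#' the steady-state response of each category is a sum of sinusoids at
#' harmonics of that category's presentation rate, with per-zone amplitudes
#' from the subject specification, a common per-subject random phase per
#' harmonic, and the linear contrast fade-in/plateau/fade-out envelope.
#' 1/f background noise (channel-wise independent) and frontally-weighted
#' biphasic blink transients are added. Event markers at each sequence onset
#' carry the condition label.
#'
#' @param spec An [subject_spec()].
#' @param design An [make_design()] design.
#' @param montage An [biosemi_montage()] montage containing every zone
#'   electrode named in `spec`.
#' @param fs Sampling rate in Hz (default 512). Must exceed twice the highest
#'   injected harmonic frequency.
#' @param condition_cv Coefficient of variation of the mean-preserving
#'   lognormal factor applied per condition (rate mapping) to each zone's
#'   summed amplitude (default 0, i.e. both rate mappings receive identical
#'   amplitudes).
#' @param zones Named list mapping zone labels to electrode sets (default
#'   [roi_definitions()]).
#' @return A list with elements `recording` (class `ft_recording`: `samples`
#'   time-by-channel matrix in microvolts, `fs`, `labels`, `montage`,
#'   `events` data.frame with `time`/`label`, `units`) and `ground_truth`
#'   (class `ft_ground_truth`: injected per-channel amplitude array
#'   \[channel, harmonic, category, condition\] at full-contrast plateau,
#'   phases, per-condition zone sums, blink times, seed).
#' @export
simulate_subject_eeg <- function(spec, design, montage, fs = 512,
                                 condition_cv = 0, zones = roi_definitions()) {
  stopifnot(inherits(spec, "ft_subject_spec"), inherits(design, "ft_design"),
            inherits(montage, "ft_montage"))
  K <- length(spec$face_harmonic_amps[[1]])
  zl <- unique(c(names(spec$face_harmonic_amps), names(spec$house_harmonic_amps)))
  unknown <- setdiff(zl, names(zones))
  if (length(unknown))
    ft_stop("unknown ROI zone label(s) in subject spec: %s", "ft_montage_error",
            paste(unknown, collapse = ", "))
  missing_el <- setdiff(unlist(zones[zl]), montage$label)
  if (length(missing_el))
    ft_stop("montage lacks zone electrode(s): %s", "ft_montage_error",
            paste(missing_el, collapse = ", "))
  fmax <- K * max(design$f_face, design$f_house)
  if (fs < 2 * fmax)
    ft_stop("sampling rate %g Hz below Nyquist for harmonic %g Hz",
            "ft_aliasing_error", fs, fmax)

  gap <- design$inter_sequence_gap
  dur <- design$sequence_duration
  nseq <- design$n_sequences
  n_seq_samp <- round(dur * fs)
  onsets <- gap + (seq_len(nseq) - 1) * (dur + gap)
  total <- gap + nseq * dur + (nseq - 1) * gap + gap
  n <- round(total * fs)
  nch <- nrow(montage)
  conds <- unique(design$sequences$condition)

  with_seed(spec$seed, {
    phases <- matrix(runif(2 * K, 0, 2 * pi), K, 2,
                     dimnames = list(NULL, c("faces", "houses")))

    # Per-condition zone sums: subject mean times a lognormal condition factor.
    clog <- sqrt(log(1 + condition_cv^2))
    draw_cond_amps <- function(base_amps) {
      lapply(conds, function(cond) {
        out <- lapply(base_amps, function(a) {
          f_c <- if (condition_cv > 0) exp(rnorm(1, -clog^2 / 2, clog)) else 1
          target <- sum(a[seq_len(min(3, K))]) * f_c
          decay <- if (K > 1 && a[1] > 0) a[2] / a[1] else 0.5
          split_sum(target, K, decay)
        })
        names(out) <- names(base_amps)
        out
      })
    }
    famps_cond <- draw_cond_amps(spec$face_harmonic_amps)
    hamps_cond <- draw_cond_amps(spec$house_harmonic_amps)
    names(famps_cond) <- names(hamps_cond) <- conds

    # channel x harmonic x category x condition injected (signed) amplitudes;
    # topographies are balanced to zero mean so common average referencing
    # leaves them unchanged.
    chan_amps <- array(0, c(nch, K, 2, length(conds)),
                       dimnames = list(montage$label, NULL,
                                       c("faces", "houses"), conds))
    for (ci in seq_along(conds)) for (k in seq_len(K)) {
      fa <- vapply(famps_cond[[ci]], `[`, 0, k)
      ha <- vapply(hamps_cond[[ci]], `[`, 0, k)
      chan_amps[, k, "faces", ci] <-
        center_topography(zone_channel_amps(fa, montage, zones), montage)
      chan_amps[, k, "houses", ci] <-
        center_topography(zone_channel_amps(ha, montage, zones), montage)
    }

    # Background noise (skipped entirely when noiseless for exact tests).
    if (spec$noise_scale > 0) {
      samples <- pink_noise(n, nch, fs, spec$noise_scale, spec$noise_alpha,
                            spec$noise_floor)
    } else {
      samples <- matrix(0, n, nch)
    }

    # Steady-state responses.
    t_rel <- (seq_len(n_seq_samp) - 1) / fs
    fade <- design$fade_duration
    env <- pmin(1, pmin(t_rel, dur - t_rel - 1 / fs) / fade)
    env <- pmax(env, 0)
    # one signal block per condition (both categories, all harmonics), added
    # to every sequence of that condition
    for (ci in seq_along(conds)) {
      srow <- design$sequences[match(conds[ci], design$sequences$condition), ]
      block <- matrix(0, n_seq_samp, nch)
      for (cat_i in 1:2) {
        rate <- if (cat_i == 1) srow$face_rate else srow$house_rate
        A <- chan_amps[, , cat_i, ci, drop = FALSE]
        dim(A) <- c(nch, K)
        if (all(A == 0)) next
        core <- vapply(seq_len(K), function(k)
          env * sin(2 * pi * k * rate * t_rel + phases[k, cat_i]),
          numeric(n_seq_samp))
        block <- block + core %*% t(A)
      }
      for (s in which(design$sequences$condition == conds[ci])) {
        idx <- round(onsets[s] * fs) + seq_len(n_seq_samp)
        samples[idx, ] <- samples[idx, ] + block
      }
    }

    # Blinks: Poisson events, frontally weighted biphasic transient.
    blink_times <- numeric(0)
    if (spec$blink_rate > 0 && spec$blink_amp != 0) {
      nb <- stats::rpois(1, spec$blink_rate * total)
      if (nb > 0) {
        blink_times <- sort(runif(nb, 0, total - 0.5))
        tmpl <- blink_template(fs)
        P <- montage_positions(montage)
        dfront <- angular_dist(P, montage_positions(montage, "Fpz")[1, ])
        wfront <- spec$blink_amp * exp(-dfront^2 / (2 * 0.5^2))
        for (bt in blink_times) {
          idx <- round(bt * fs) + seq_along(tmpl)
          samples[idx, ] <- samples[idx, ] + outer(tmpl, as.numeric(wfront))
        }
      }
    }

    rec <- structure(list(
      samples = samples, fs = fs, labels = montage$label, montage = montage,
      events = data.frame(time = onsets, label = design$sequences$condition,
                          stringsAsFactors = FALSE),
      units = "uV"), class = "ft_recording")
    gt <- structure(list(
      channel_amps = chan_amps, phases = phases,
      zone_sums = list(faces = famps_cond, houses = hamps_cond),
      conditions = conds, seq_condition = design$sequences$condition,
      blink_times = blink_times, subject_id = spec$subject_id,
      seed = spec$seed), class = "ft_ground_truth")
    list(recording = rec, ground_truth = gt)
  })
}

#' @export
print.ft_recording <- function(x, ...) {
  cat(sprintf("ft_recording: %d channels x %.1f s @ %g Hz, %d events\n",
              ncol(x$samples), nrow(x$samples) / x$fs, x$fs, nrow(x$events)))
  invisible(x)
}

#' Injected ground-truth summed amplitude for a zone and category
#'
#' Returns the injected per-zone summed amplitude over the first `n_harmonics`
#' harmonics (full-contrast plateau, microvolts), averaged over the
#' counterbalanced conditions -- the quantity the analysis pipeline estimates
#' as the summed baseline-corrected response.
#'
#' @param gt An `ft_ground_truth`.
#' @param zone Zone label (e.g. `"LOT"`).
#' @param category `"faces"` or `"houses"`.
#' @param n_harmonics Number of leading harmonics to sum (default 3).
#' @return Numeric scalar, microvolts.
#' @export
gt_injected_sum <- function(gt, zone, category = c("faces", "houses"),
                            n_harmonics = 3) {
  category <- match.arg(category)
  per_cond <- vapply(gt$zone_sums[[category]], function(za)
    sum(za[[zone]][seq_len(n_harmonics)]), 0)
  mean(per_cond)
}

#' Simulate a full synthetic cohort of frequency-tagging recordings
#'
#' Draws subject specifications with [make_cohort_specs()] (TD subjects with
#' differentiated face/house topographies, ASD subjects undifferentiated,
#' group-specific SRS T-scores) and realizes each subject's recording. Two
#' calls with the same seed return identical cohorts.
#'
#' For large cohorts at full duration this holds all recordings in memory;
#' prefer [analyze_cohort()], which streams subject by subject, for
#' end-to-end analysis.
#'
#' @param n_per_group Subjects per group.
#' @param effect_config An [cohort_effects()] configuration.
#' @param seed Integer cohort seed.
#' @param design,montage,fs Passed to [simulate_subject_eeg()].
#' @return A list with `subjects` (named list of
#'   `list(recording, ground_truth)`), `subject_table`, `specs`, and the
#'   behavioural table `behavior` (per-subject accuracy and mean RT realized
#'   with [simulate_task_events()]).
#' @export
simulate_cohort <- function(n_per_group = 21, effect_config = cohort_effects(),
                            seed = 1L, design = make_design(),
                            montage = biosemi_montage(), fs = 512) {
  cs <- make_cohort_specs(n_per_group, effect_config, seed, design)
  subjects <- lapply(cs$specs, simulate_subject_eeg, design = design,
                     montage = montage, fs = fs,
                     condition_cv = effect_config$cell_cv)
  behavior <- cohort_behavior(cs, design)
  list(subjects = subjects, subject_table = cs$subject_table,
       specs = cs$specs, behavior = behavior)
}

# Realize task behaviour for every subject of a cohort spec.
cohort_behavior <- function(cohort_specs, design) {
  cfg <- cohort_specs$effect_config
  st <- cohort_specs$subject_table
  rows <- lapply(seq_len(nrow(st)), function(i) {
    grp <- st$group[i]
    ev <- simulate_task_events(design, accuracy = cfg$accuracy[[grp]],
                               mean_rt = cfg$mean_rt[[grp]],
                               seed = derive_seed(st$seed[i], 7))
    data.frame(subject = st$subject[i], group = grp,
               accuracy = mean(ev$responded),
               mean_rt = mean(ev$rt[ev$responded], na.rm = TRUE))
  })
  do.call(rbind, rows)
}
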