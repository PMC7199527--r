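#' Group-level cohort configuration for the synthetic generator
#'
#' Bundles every tunable of the synthetic cohort: the group-mean summed
#' harmonic amplitudes per ROI zone and stimulus category, between-subject and
#' within-cell variability, the harmonic decay profile, noise and blink
#' parameters, and the SRS T-score distributions. Defaults encode the study
#' conditions the generator emulates: typically developing (TD) children show
#' differentiated topographies (faces > houses over lateral occipito-temporal
#' cortex, houses > faces medially) while the ASD group is undifferentiated,
#' and SRS T-scores are drawn from group-specific truncated Gaussians.
#'
#' Amplitudes are expressed as the *summed baseline-corrected amplitude over
#' the first three harmonics* (the quantity the pipeline estimates, in
#' microvolts); the generator divides each sum across harmonics using the
#' decay profile `A_k = A_1 * decay^(k-1)`.
#'
#' @param face_sums,house_sums Named lists `list(TD = c(MO=, LOT=, ROT=),
#'   ASD = ...)` of group-mean summed amplitudes in microvolts.
#' @param subject_cv Between-subject coefficient of variation of a
#'   mean-preserving lognormal factor applied to all of a subject's cells
#'   (default 0.30). Multiplicative variation keeps amplitudes positive and
#'   right-skewed, as evoked response amplitudes are.
#' @param cell_cv Within-subject coefficient of variation of the independent
#'   lognormal factor applied to each cell-by-rate observation (default 0.25).
#' @param n_harmonics Number of injected harmonics per rate (default 4).
#' @param harmonic_decay Geometric decay of successive harmonic amplitudes
#'   (default 0.5, i.e. each harmonic is half the previous one).
#' @param noise_scale Total RMS of the 1/f background noise per channel in
#'   microvolts (default 15, typical of paediatric scalp EEG).
#' @param noise_alpha Spectral exponent of the background (power ~ 1/f^alpha,
#'   default 1).
#' @param noise_floor Relative white-noise floor mixed into the 1/f background
#'   (default 0.1).
#' @param blink_rate Blink events per second (default 0.36).
#' @param blink_amp Peak blink amplitude at frontal channels in microvolts
#'   (default 100).
#' @param compensate_floor Interpret the configured sums as target *measured*
#'   baseline-corrected amplitudes: the generator adds the analytic
#'   noise-floor offset of the baseline-correction estimator
#'   ([expected_noise_floor()]) to the injected truth, so the pipeline's
#'   output means match the configured values (default `TRUE`). Published
#'   cell means in this literature are baseline-corrected, i.e.
#'   floor-subtracted, estimates; injecting them uncompensated would
#'   reproduce neither the reported amplitudes nor universal individual
#'   significance.
#' @param srs Named list of `c(mean, sd)` per group for SRS T-scores
#'   (defaults ASD 85 +/- 12, TD 42 +/- 6; truncated to \[30, 120\]).
#' @param accuracy,mean_rt Behavioural task defaults per group (named vectors).
#' @return A list of class `ft_effect_config`.
#' @export
cohort_effects <- function(
    face_sums = list(TD = c(MO = 1.44, LOT = 1.32, ROT = 1.26),
                     ASD = c(MO = 1.30, LOT = 0.95, ROT = 0.95)),
    house_sums = list(TD = c(MO = 1.82, LOT = 0.75, ROT = 0.91),
                      ASD = c(MO = 1.49, LOT = 0.76, ROT = 0.77)),
    subject_cv = 0.30, cell_cv = 0.25,
    n_harmonics = 4, harmonic_decay = 0.5,
    noise_scale = 15, noise_alpha = 1, noise_floor = 0.1,
    blink_rate = 0.36, blink_amp = 100, compensate_floor = TRUE,
    srs = list(TD = c(mean = 42, sd = 6), ASD = c(mean = 85, sd = 12)),
    accuracy = c(TD = 0.971, ASD = 0.97),
    mean_rt = c(TD = 0.46, ASD = 0.47)) {
  structure(as.list(environment()), class = "ft_effect_config")
}

#' Null (no-effect) cohort configuration
#'
#' Same variance/noise structure as [cohort_effects()] but with every cell mean
#' set to the grand mean, so groups, stimulus types and ROIs are exchangeable.
#' Used for type-I error calibration.
#'
#' @param ... Overrides passed on to [cohort_effects()].
#' @return An `ft_effect_config`.
#' @export
null_effects <- function(...) {
  cfg <- cohort_effects(...)
  gm <- mean(c(unlist(cfg$face_sums), unlist(cfg$house_sums)))
  flat <- c(MO = gm, LOT = gm, ROT = gm)
  cfg$face_sums <- list(TD = flat, ASD = flat)
  cfg$house_sums <- list(TD = flat, ASD = flat)
  cfg
}

# Split a summed first-3-harmonic amplitude into per-harmonic amplitudes using
# the geometric decay profile. sum over k=1..3 of A1*decay^(k-1) = target.
split_sum <- function(target, n_harmonics, decay, n_summed = 3) {
  a1 <- target / sum(decay^(seq_len(min(n_summed, n_harmonics)) - 1))
  a1 * decay^(seq_len(n_harmonics) - 1)
}

#' Specify one synthetic subject
#'
#' Per-subject ground-truth parameters: the per-ROI-zone amplitudes injected at
#' harmonics of the face and house rates, the background noise scale, the
#' blink rate, and a seed that reproducibly determines the realization.
#'
#' @param subject_id Character id.
#' @param group `"TD"` or `"ASD"`.
#' @param srs_t SRS T-score.
#' @param face_harmonic_amps,house_harmonic_amps Named lists (`MO`, `LOT`,
#'   `ROT`) of non-negative per-harmonic amplitude vectors in microvolts
#'   (harmonics 1..K of the respective rate, full-contrast plateau values).
#' @param noise_scale RMS of 1/f background noise (microvolts).
#' @param noise_alpha,noise_floor Background-noise shape parameters.
#' @param blink_rate Blinks per second (>= 0).
#' @param blink_amp Peak frontal blink amplitude (microvolts).
#' @param seed Integer seed for this subject's realization.
#' @return A list of class `ft_subject_spec`.
#' @export
subject_spec <- function(subject_id, group = c("TD", "ASD"), srs_t = 50,
                         face_harmonic_amps, house_harmonic_amps,
                         noise_scale = 15, noise_alpha = 1, noise_floor = 0.1,
                         blink_rate = 0.36, blink_amp = 100, seed = 1L) {
  group <- match.arg(group)
  check_amps <- function(a, what) {
    if (!is.list(a) || is.null(names(a)))
      ft_stop("%s must be a named list of per-zone amplitude vectors",
              "ft_spec_error", what)
    if (any(unlist(a) < 0))
      ft_stop("%s must be non-negative", "ft_spec_error", what)
  }
  check_amps(face_harmonic_amps, "face_harmonic_amps")
  check_amps(house_harmonic_amps, "house_harmonic_amps")
  if (blink_rate < 0) ft_stop("blink_rate must be >= 0", "ft_spec_error")
  structure(list(
    subject_id = as.character(subject_id), group = group, srs_t = srs_t,
    face_harmonic_amps = face_harmonic_amps,
    house_harmonic_amps = house_harmonic_amps,
    noise_scale = noise_scale, noise_alpha = noise_alpha,
    noise_floor = noise_floor,
    blink_rate = blink_rate, blink_amp = blink_amp,
    seed = as.integer(seed)), class = "ft_subject_spec")
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Draw the subject specifications for a synthetic cohort
#'
#' Samples per-subject injected amplitudes around the group means of an effect
#' configuration (a mean-preserving lognormal subject factor shared across
#' cells), SRS T-scores from group-specific truncated Gaussians, and
#' per-subject seeds -- everything needed to realize each subject's recording
#' with [simulate_subject_eeg()]. Per-condition (rate mapping) amplitude
#' variation is drawn later, inside the EEG simulator, from the subject seed.
#'
#' @param n_per_group Subjects per group (TD and ASD).
#' @param effect_config An [cohort_effects()] configuration.
#' @param seed Integer cohort seed; the whole cohort is reproducible from it.
#' @param design The `ft_design` the cohort will be recorded under (used for
#'   the analytic floor compensation; default [make_design()]).
#' @return A list with `specs` (list of `ft_subject_spec`),
#'   `subject_table` (data.frame: subject, group, srs_t, seed) and
#'   `cell_targets` (per subject: the drawn mean summed amplitude per
#'   category x zone before per-condition jitter).
#' @export
make_cohort_specs <- function(n_per_group = 21, effect_config = cohort_effects(),
                              seed = 1L, design = make_design()) {
  if (n_per_group < 1) ft_stop("n_per_group must be >= 1", "ft_spec_error")
  cfg <- effect_config
  # analytic offset of the baseline-correction estimator at this noise level:
  # added to the injected truth so measured sums land on the configured means.
  # First order, the estimator reads S - floor per harmonic; second order, the
  # Rice small-signal term adds back ~ s^2 / 2A (s = floor / sqrt(pi/2)).
  phi_for <- function(target) 0
  if (isTRUE(cfg$compensate_floor) && cfg$noise_scale > 0) {
    hs <- default_harmonic_sets(design)
    n_avg <- max(1, design$n_sequences / 2)
    # crop duration (whole 2-s blocks of the plateau) at the acquisition rate
    n_crop <- floor(design$full_contrast_duration / 2) * 2 * 512
    floors <- rowMeans(vapply(hs, function(h)
      expected_noise_floor(h$harmonics, cfg$noise_scale, cfg$noise_alpha,
                           cfg$noise_floor, n_samples = n_crop,
                           n_avg = n_avg), numeric(3)))
    phi_for <- function(target) {
      if (target <= 0) return(0)
      A <- split_sum(target, 3, cfg$harmonic_decay)
      rice <- (floors^2 / (pi / 2)) / (2 * pmax(A, 2 * floors))
      sum(floors) - sum(rice)
    }
  }
  with_seed(seed, {
    specs <- list(); rows <- list(); targets <- list()
    i <- 0
    for (grp in c("TD", "ASD")) for (j in seq_len(n_per_group)) {
      i <- i + 1
      sid <- sprintf("S%02d_%s", i, grp)
      # subject-level lognormal factor, mean 1, CV = subject_cv, all cells
      slog <- sqrt(log(1 + cfg$subject_cv^2))
      f_s <- exp(rnorm(1, -slog^2 / 2, slog))
      mk <- function(sums) {
        zones <- names(sums[[grp]])
        out <- lapply(zones, function(z) {
          target <- sums[[grp]][[z]] * f_s
          split_sum(target + phi_for(target), cfg$n_harmonics,
                    cfg$harmonic_decay)
        })
        names(out) <- zones
        out
      }
      famps <- mk(cfg$face_sums); hamps <- mk(cfg$house_sums)
      srs_par <- cfg$srs[[grp]]
      srs_t <- round(rtrunc_norm(1, srs_par[["mean"]], srs_par[["sd"]], 30, 120))
      sseed <- derive_seed(seed, i)
      specs[[sid]] <- subject_spec(
        sid, grp, srs_t, famps, hamps,
        noise_scale = cfg$noise_scale, noise_alpha = cfg$noise_alpha,
        noise_floor = cfg$noise_floor,
        blink_rate = cfg$blink_rate, blink_amp = cfg$blink_amp, seed = sseed)
      rows[[sid]] <- data.frame(subject = sid, group = grp, srs_t = srs_t,
                                seed = sseed)
      targets[[sid]] <- list(
        faces = vapply(famps, function(a) sum(a[1:3]), 0),
        houses = vapply(hamps, function(a) sum(a[1:3]), 0))
    }
    list(specs = specs,
         subject_table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         cell_targets = targets,
         effect_config = cfg, seed = seed, n_per_group = n_per_group)
  })
}
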