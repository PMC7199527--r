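#' Build a two-stream frequency-tagging stimulation design
#'
#' Defines the stimulation protocol for an experiment in which two superimposed
#' image streams (canonically faces and houses) flicker at distinct rates. Each
#' sequence presents one category at `face_rate` and the other at `house_rate`;
#' the rate-to-category mapping is counterbalanced so that each mapping occurs
#' in exactly half of the sequences. The base frequency -- the largest common
#' divisor of the two rates -- determines the cycle length used later when
#' cropping segments so that both rates fall exactly on FFT bins.
#'
#' @param face_rate,house_rate Presentation rates in Hz (defaults 6 and 7.5).
#'   Must differ and share a positive common divisor.
#' @param n_sequences Number of stimulation sequences; must be even so the two
#'   rate-to-category mappings can be counterbalanced.
#' @param full_contrast_duration Seconds of stimulation at full contrast per
#'   sequence (default 60).
#' @param fade_duration Seconds of linear contrast fade-in and fade-out
#'   flanking the plateau (default 2; a sequence lasts
#'   `full_contrast_duration + 2 * fade_duration` seconds).
#' @param contrast_max Maximum stimulus contrast as a fraction (default 0.5).
#' @param n_color_changes Number of brief outline colour changes per sequence
#'   used for the orthogonal attention task (default 15).
#' @param color_change_duration Duration of each colour change in seconds
#'   (default 0.3).
#' @param inter_sequence_gap Seconds of stimulation-free recording between
#'   sequences (default 5), sized so that segmentation windows extending 2 s
#'   before and 5 s after a sequence never overlap a neighbouring sequence.
#'
#' @return An object of class `ft_design`: a list with the fields above plus
#'   `base_frequency` (Hz), `sequence_duration` (s) and `sequences`, a
#'   data.frame with one row per sequence giving `face_rate`, `house_rate` and
#'   the `condition` label (`"faces6_houses7.5"` or `"faces7.5_houses6"`).
#' @examples
#' d <- make_design(6, 7.5, 4)
#' d$base_frequency        # 1.5
#' table(d$sequences$condition)
#' @export
make_design <- function(face_rate = 6, house_rate = 7.5, n_sequences = 4,
                        full_contrast_duration = 60, fade_duration = 2,
                        contrast_max = 0.5, n_color_changes = 15,
                        color_change_duration = 0.3, inter_sequence_gap = 5) {
  if (face_rate <= 0 || house_rate <= 0)
    ft_stop("presentation rates must be positive", "ft_design_error")
  if (isTRUE(all.equal(face_rate, house_rate)))
    ft_stop("face and house rates must differ (got %g and %g)",
            "ft_design_error", face_rate, house_rate)
  if (n_sequences %% 2 != 0 || n_sequences < 2)
    ft_stop("n_sequences must be even (>= 2) to counterbalance the rate-to-category mapping",
            "ft_counterbalance_error")
  base <- rational_gcd(face_rate, house_rate)
  if (base <= 0)
    ft_stop("rates share no positive common divisor", "ft_design_error")

  cond_label <- function(fr, hr) sprintf("faces%g_houses%g", fr, hr)
  # Alternate the two mappings A, B, A, B ... : each occurs n_sequences/2 times.
  flip <- (seq_len(n_sequences) %% 2) == 0
  seqs <- data.frame(
    sequence = seq_len(n_sequences),
    face_rate = ifelse(flip, house_rate, face_rate),
    house_rate = ifelse(flip, face_rate, house_rate)
  )
  seqs$condition <- cond_label(seqs$face_rate, seqs$house_rate)

  structure(list(
    f_face = face_rate, f_house = house_rate,
    base_frequency = base,
    n_sequences = n_sequences,
    full_contrast_duration = full_contrast_duration,
    fade_duration = fade_duration,
    contrast_max = contrast_max,
    n_color_changes = n_color_changes,
    color_change_duration = color_change_duration,
    inter_sequence_gap = inter_sequence_gap,
    sequence_duration = full_contrast_duration + 2 * fade_duration,
    sequences = seqs
  ), class = "ft_design")
}

#' @export
print.ft_design <- function(x, ...) {
  cat(sprintf(
    "Frequency-tagging design: %g vs %g Hz (base %g Hz), %d sequences of %g s\n",
    x$f_face, x$f_house, x$base_frequency, x$n_sequences, x$sequence_duration))
  cat(sprintf("  %g s full contrast + 2 x %g s fade, contrast max %.0f%%\n",
              x$full_contrast_duration, x$fade_duration, 100 * x$contrast_max))
  invisible(x)
}

#' Simulate orthogonal-task behaviour for a stimulation design
#'
#' Generates the colour-change detection events used to keep participants
#' attending: per sequence, `n_color_changes` brief changes are placed at
#' uniformly random, non-overlapping onsets; each is detected with probability
#' `accuracy`, and detected events receive a reaction time drawn from a gamma
#' distribution with the requested mean.
#'
#' @param design An `ft_design`.
#' @param accuracy Detection probability in \[0, 1\] (default 0.971).
#' @param mean_rt Mean reaction time in seconds (default 0.46); RTs are
#'   gamma-distributed (shape 10) so they are strictly positive.
#' @param seed Integer seed; the realization is reproducible.
#' @return A data.frame with columns `sequence`, `onset` (s, within sequence),
#'   `responded` (logical) and `rt` (s; `NA` for misses).
#' @export
simulate_task_events <- function(design, accuracy = 0.971, mean_rt = 0.46,
                                 seed = 1L) {
  stopifnot(inherits(design, "ft_design"))
  if (accuracy < 0 || accuracy > 1)
    ft_stop("accuracy must lie in [0, 1]", "ft_behavior_error")
  if (mean_rt <= 0) ft_stop("mean_rt must be positive", "ft_behavior_error")
  n <- design$n_color_changes
  dur <- design$sequence_duration
  w <- design$color_change_duration
  if (n * w > dur)
    ft_stop("cannot place %d events of %g s without overlap in a %g s sequence",
            "ft_scheduling_error", n, w, dur)
  with_seed(seed, {
    rows <- lapply(seq_len(design$n_sequences), function(s) {
      # Rejection-sample non-overlapping onsets.
      for (try in 1:1000) {
        on <- sort(runif(n, 0, dur - w))
        if (n == 1 || all(diff(on) >= w)) {
          hit <- runif(n) < accuracy
          rt <- ifelse(hit, rgamma(n, shape = 10, rate = 10 / mean_rt), NA_real_)
          return(data.frame(sequence = s, onset = on, responded = hit, rt = rt))
        }
      }
      ft_stop("failed to schedule %d non-overlapping events", "ft_scheduling_error", n)
    })
    do.call(rbind, rows)
  })
}
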