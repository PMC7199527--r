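---
title: "Frequency-tagging analysis of superimposed stimulus streams: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-tagging analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpvstag)
```

# The experimental paradigm

In a fast periodic visual stimulation (FPVS) experiment with frequency
tagging, two image streams are superimposed and flicker at distinct rates --
canonically faces at 6 Hz and houses at 7.5 Hz. Because the brain's
steady-state response is locked to each stream's rate and its integer
harmonics, the two responses can be separated perfectly in the frequency
domain even though the stimuli overlap in space and time. Each 64-s sequence
carries 60 s of full-contrast stimulation flanked by 2-s contrast fades, the
rate-to-category mapping is counterbalanced across sequences so that category
effects cannot be confounded with rate effects, and an orthogonal
colour-change detection task keeps participants attending without requiring
any judgement about the stimuli. The scientific question this design serves
is whether social stimuli (faces) receive preferential neural processing:
typically developing children show a differentiated topography (faces >
houses over lateral occipito-temporal cortex, houses > faces medially),
whereas children with autism spectrum disorder show no such modulation.

`fpvstag` implements the complete analysis chain for such experiments --
preprocessing, high-resolution amplitude spectra, local-noise statistics,
harmonic selection and summation, individual-subject significance, and
group-level mixed-effects inference -- together with a synthetic cohort
generator that provides exact ground truth for every stage.

# The synthetic cohort generator

## Signal model

Each subject's recording is

$$x_c(t) = \sum_{\mathrm{cat}} \sum_{k=1}^{K} A_{c,k,\mathrm{cat}}
  \, e(t)\, \sin(2\pi k f_{\mathrm{cat}} t + \varphi_{k,\mathrm{cat}})
  \;+\; \eta_c(t) \;+\; b_c(t),$$

where $e(t)$ is the linear fade-in / plateau / fade-out contrast envelope,
$\eta_c$ is $1/f^\alpha$ background noise and $b_c$ a blink process. The
defaults encode the study conditions the generator emulates:

* **Stimulation**: 6 vs 7.5 Hz, four 64-s sequences (60 s plateau, 2-s
  fades), counterbalanced, separated by 5-s gaps so the 67-s segmentation
  windows never overlap adjacent sequences.
* **Amplitudes**: injected per ROI zone as the *summed* amplitude of the
  first three harmonics, divided across $K = 4$ harmonics with geometric
  decay $A_k = A_1 2^{-(k-1)}$ -- a plausible steady-state roll-off. Group
  means are the observed cell means of the emulated study (e.g. TD LOT:
  faces 1.32 uV, houses 0.75 uV; ASD LOT: 0.95 vs 0.76 uV), so TD subjects
  are differentiated and ASD subjects are not.
* **Topography**: parametric weights, not a forward model. Channels inside a
  zone receive exactly the zone amplitude; other channels receive a
  Gaussian-decayed fraction (angular distance, sd 0.3 rad). Each topography
  is then balanced by an opposite-phase frontal far field (truncated
  Gaussian around Fpz, identically zero beyond 1.5 rad) so the signed
  amplitude pattern sums to zero across the cap. Real average-referenced
  topographies are zero-mean in exactly this sense, and the balance makes
  common-average re-referencing leave every injected amplitude untouched --
  without it, the reference would subtract the scalp mean of the topography
  and no amplitude-recovery test could be exact.
* **Phases** $\varphi_{k,\mathrm{cat}}$ are drawn once per subject: the
  analysis averages segments within subject only, so phase never matters
  downstream, but it must be stable within a subject for time-domain
  averaging to preserve the signal.
* **Variability** is multiplicative and mean-preserving: a lognormal
  subject factor (CV 0.30) shared by all cells, and an independent lognormal
  factor (CV 0.25) per cell and rate mapping. Evoked amplitudes are positive
  and right-skewed; additive Gaussian variation of comparable size would
  produce physically impossible near-zero or negative responses in the lower
  cells. The CVs were fixed a priori by a non-central-F power calculation so
  that the three-way interaction is detectable in most 21-per-group cohorts
  (see *Statistical layer*).
* **Noise**: $1/f^{\alpha}$ with $\alpha = 1$ plus a 10% white floor,
  channel-wise independent, total RMS 15 uV per channel -- typical of
  paediatric scalp EEG after minimal preprocessing. The model deliberately
  omits alpha-band peaks and spatial noise correlation: it is the simplest
  process that yields realistic behaviour of the 20-bin local-noise
  statistics, which is what the pipeline estimates.
* **Blinks**: a Poisson train (0.36/s, the emulated study's reported mean)
  of 400-ms biphasic transients, peak 100 uV at Fpz with Gaussian spatial
  decay. Blink energy is broadband, so it raises the local noise floor
  rather than contaminating specific stimulation bins -- which is why the
  pipeline, like the study it follows, applies no blink correction by
  default.
* **SRS T-scores**: Gaussian, ASD 85 +/- 12 and TD 42 +/- 6, truncated to
  [30, 120].
* **Behaviour**: 15 colour changes per sequence, detected with probability
  0.971 (TD) / 0.97 (ASD), gamma reaction times with means 0.46 / 0.47 s.

What passing tests on this generator do *not* show: robustness to volume
conduction, correlated noise, alpha intrusions, movement artifacts, or
drop-outs -- none of which the generator emulates. They do show that every
algorithmic stage is correct, calibrated and unbiased under a known model.

## Determinism

Every random quantity derives from one integer seed: cohort seeds spawn
per-subject seeds through a fixed integer recurrence, and all generators
restore the caller's RNG state. Identical seeds give bit-identical cohorts.

# Preprocessing

The chain is fixed: segment, band-pass, resample, interpolate, re-reference;
each step stamps a provenance flag. Interpolation and re-referencing do not
commute exactly, so the order is part of the contract.

* **Segmentation** anchors on the full-contrast plateau: a segment spans
  `pre` s before the plateau to `post` s after it, so the default 2 + 60 + 5
  = 67-s window starts exactly at the sequence onset (the 2-s fade-in fills
  the pre-window).
* **Filtering** is a zero-phase (forward-backward) Butterworth band-pass,
  0.1--100 Hz, order 4. Zero-phase filtering is chosen so that
  stimulation-locked phase is not distorted; pass-band loss at 6 Hz is below
  0.01%.
* **Resampling** 512 to 256 Hz is exact decimation (the prior 100-Hz
  low-pass serves as the anti-alias filter, Nyquist after decimation being
  128 Hz); non-integer ratios fall back to polyphase resampling.
* **Bad channels** are a user-supplied list (at most 5% of the cap, i.e. 3
  of 64), replaced by the inverse-distance-weighted mean of the three
  nearest good electrodes. "Linear interpolation from the three nearest
  electrodes" under-determines the weights; inverse distance is the natural
  choice and reduces to the plain mean for equidistant neighbours. An
  optional variance-threshold detector (`detect_bad_channels()`) is
  provided but off by default, since no automatic criterion was specified.

# Spectral statistics

Segments are cropped, starting at the first sample after fade-in, to the
largest whole number of base-frequency cycles (base = largest common divisor
of the two rates, 1.5 Hz) whose duration is a whole number of samples. At
256 Hz the smallest such block is 3 cycles = 512 samples = 2 s, so the crop
is 60 s = 15360 samples and the resolution is 1/60 ~ 0.017 Hz; both rates
then fall exactly on bin centres. A requested frequency that misses the grid
by more than df/100 raises an error rather than being snapped silently.

Amplitude spectra use the one-sided 2/N scaling so a sinusoid of amplitude
A uV reads A uV at its bin. Three statistics are computed against a local
noise neighbourhood of 12 bins per side, excluding the two bins adjacent to
the target and the two most extreme remaining bins (single maximum and
single minimum, ties resolved toward lower frequency), leaving 20 noise
bins:

* **SNR** = amplitude / noise mean (scale-invariant),
* **baseline-corrected amplitude** = amplitude - noise mean (uV, summable
  across harmonics),
* **z-score** = (amplitude - noise mean) / noise SD (significance of a
  peak).

The identity `baseline = noise_mean * (SNR - 1)` holds bin-wise and is
asserted in the tests.

## Calibration of the z statistic

Amplitude bins are Rayleigh-distributed, not Gaussian, and excluding the
extreme bins shrinks the local SD, so the single-bin z statistic is
anti-conservative: Monte-Carlo calibration gives P(z > 1.64) ~ 0.116 on pure
noise rather than the nominal 0.05. The individual-significance statistic
used for subjects (below) sums three harmonics and uses 36 noise bins, which
brings its false-positive rate to ~0.09. The tests freeze these
Monte-Carlo-derived rates rather than the nominal level.

## The noise-floor offset of baseline correction

At a bin carrying a strong signal $S$ with per-bin noise scale $s$, the
expected raw amplitude is $\approx S + s^2/2S$ (Rice), while baseline
correction subtracts the full local floor $E|N| = s\sqrt{\pi/2}$. The
baseline-corrected estimate of a strong response is therefore offset by
about $-1.25\,s$ per harmonic -- roughly $-0.33$ uV on a three-harmonic sum
at the default 15 uV background after two-segment averaging
(`expected_noise_floor()` computes the per-bin floor in closed form from the
noise model, with the per-bin density set by the acquisition-rate bandwidth
over which the total RMS is spread; the prediction agrees with measured
floors to a few percent).
The offset is identical at every harmonic bin and ROI, so *differences*
between conditions, ROIs and groups -- everything the inferential layer
tests -- are unaffected.

Two consequences are built into the package. First, the generator's default
amplitude tables are target *measured* baseline-corrected sums: published
cell means in this literature are floor-subtracted estimates of a larger
underlying response, so the generator adds the analytic floor offset to the
injected truth (`compensate_floor = TRUE`). Without the compensation a
synthetic cohort would reproduce neither the configured cell means nor the
universal individual-level significance that high-SNR frequency tagging
yields, because weak cells would be pushed toward zero twice -- once by
nature (the means are already floor-subtracted) and once by the estimator.
Second, the parameter-recovery experiment (`recovery_experiment()`) runs at
a 1.2 uV RMS background, where the residual offset is below 2% of the
smallest cell while every response is still individually significant -- the
operating point at which recovery tests correctness rather than this known
estimator property.

# Harmonic selection and quantification

Group-level selection computes z-spectra on the grand average across *all*
subjects of both groups (and across the ROI electrodes), walks the harmonics
of each rate, and retains the consecutive run with z > 2.32 (p < 0.01,
one-tailed, strict). With four injected harmonics per rate the procedure
finds harmonics of 6 Hz significant through 30 Hz (the 7.5 Hz stream's
fourth harmonic also lands there) and harmonics of 7.5 Hz through 30 Hz.
Harmonics that are multiples of both rates (30 Hz) are then excluded and the
two sets truncated to equal length, yielding 6, 12, 18 Hz and 7.5, 15,
22.5 Hz. Baseline-corrected amplitudes are averaged across the ROI
electrodes and summed across the retained harmonics; averaging and summing
commute, which the tests assert numerically.

Individual significance follows the four-step procedure: ROI-average the raw
spectrum, cut mini-spectra of 20 bins per side around each harmonic, sum
them element-wise, and z-score the centre against the surrounding bins. One
passage of the source methodology specifies 20 bins per side here while the
main neighbourhood uses 12; we extract 20 per side and apply the standard
exclusion convention (2 adjacent + 2 extremes, leaving 36 noise bins) when
z-scoring, honouring both passages -- the difference is empirically
negligible. Significance is z > 1.64 (p < 0.05, one-tailed), strict.

The two counterbalanced rate mappings are quantified separately (the
response table is rate-resolved) and pooled by averaging the two summed
responses where a per-category value is needed (SRS correlations). The
rate-resolved table is what the mixed model consumes: with 42 subjects x 2
stimulus types x 3 ROIs x 2 rates = 504 observations.

# Statistical layer

The group model is `amplitude ~ group * stimulus * roi + (1 | subject)`,
type-III F tests with sum-to-zero contrasts. Denominator degrees of freedom
default to Satterthwaite (Kenward-Roger selectable); for the balanced
default design both give integer df: 40 for the between-subject factor and
452 for all within-subject effects. (The emulated study reports 441 with the
same design; no standard df method reproduces that figure -- Satterthwaite
and Kenward-Roger give 452 on the rate-resolved table and 200 on the pooled
table -- so the package reports the df its stated method actually yields.)
Post-hoc faces-minus-houses contrasts within each group x ROI cell are
Tukey-adjusted over the family of all pairwise comparisons among the twelve
cell means, with unstandardized estimates in uV. Singular fits are flagged,
never silent.

The generator's variance components were fixed a priori by power analysis:
with cell means as above, the three-way interaction carries a non-centrality
of about $\lambda = 42\sum_{g,c,r}\gamma^2_{gcr}/\sigma^2$; residual
variation of ~0.28 uV per observation (the lognormal CVs above) gives
$\lambda \approx 20$ and >90% power at $\alpha = .05$ with 21 subjects per
group, while the null configuration keeps the test calibrated (type-I error
~5% over hundreds of simulated cohorts). This is deliberately more sensitive
than the emulated study's marginal interaction: the generator is a testbed,
and a near-threshold default would make every downstream check a coin flip.

The time-course analysis re-crops each subject's averaged waveforms to the
largest whole-cycle block within L seconds for L = 5, 10, ..., 60, re-runs
the spectral quantification per length over the pooled occipito-temporal
electrodes (LOT + ROT; the source is ambiguous between pooling and keeping
hemisphere as a factor -- pooling is the default, the per-ROI table remains
available), and refits `amplitude ~ group * stimulus + (1 | subject)` at
each length. Because shorter segments have wider bins and hence larger noise
floors, baseline-corrected amplitudes show the characteristic buildup over
the first tens of seconds before stabilizing.

Behavioural accuracy and reaction times are compared with two-sided Welch
t-tests by default (the pooled-variance test is selectable); the realized df
is reported, with a note when it differs from n1 + n2 - 2. Spearman
correlations relate faces, houses and face-house difference amplitudes to
SRS T-scores per ROI, within each group and pooled; no correction beyond the
Tukey family is applied anywhere, matching the source analysis, and the
output says so.

# Numerical choices and edge cases

* Target frequencies must be exact bin centres (tolerance df/100); no
  silent snapping.
* Tie-breaks in extreme-bin exclusion go to the lower frequency, making the
  retained set deterministic.
* The FFT path is verified against a direct O(N^2) DFT oracle to 1e-9
  relative error; the neighbourhood logic against brute-force enumeration
  over a thousand randomized spectra.
* Noiseless injections recover exactly (< 0.5% end-to-end, limited only by
  filter ripple); a zero-amplitude, zero-noise subject yields an identically
  zero recording.
* Degenerate statistics raise typed errors: zero noise mean (SNR), zero
  noise SD (z), constant inputs (Spearman), single-channel reference,
  segments out of bounds, harmonic sets emptied by shared-harmonic
  exclusion.
* Problem sizes in the shipped tests and acceptance script -- 42-subject
  cohorts at full 64-channel/512-Hz scale, 200-subject recovery runs on the
  12-electrode ROI montage, 400-500-cohort calibration loops -- were chosen
  so the whole suite completes on a single CPU in well under half an hour
  while keeping Monte-Carlo error small relative to every asserted margin.

# Known limitations

* Topographies are parametric weights; no leadfield, so nothing can be
  concluded about source localization.
* The noise model has no alpha peak and no spatial correlation; SNR values
  at occipital electrodes in real data will differ.
* The baseline-corrected estimator's noise-floor offset (derived above) is
  inherent to the method, not corrected.
* EDF/BDF files are not read or written; recordings round-trip through the
  package's documented float32 + JSON container.
* The behavioural task model draws reaction times from a gamma distribution
  with fixed shape; it is a placeholder for realistic RT dynamics.
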