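---
title: "Task-graded spectral analysis of thalamic LFP during speech: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-graded spectral analysis of thalamic LFP during speech: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis problem

Local field potentials (LFP) recorded from deep-brain-stimulation (DBS) lead
contacts in the motor thalamus show event-locked oscillatory changes when the
patient speaks: power in the delta/theta range (1–8 Hz) rises after speech
onset, and beta power (13–30 Hz) drops before it, more strongly for motorically
complex utterances (sentence repetition) than for simple ones (a sustained
vowel). `speechersp` implements the complete analysis chain for such
experiments — three interleaved speech tasks (vowel, diadochokinesis "DDK",
sentence), bilateral four-contact leads, onset-locked trials — together with a
synthetic cohort generator that reproduces the statistical structure the
analysis assumes, so that every stage can be validated against known ground
truth without any patient recording.

The pipeline is, in order:

1. **simulate** (optional): continuous multi-channel voltages per
   participant–hemisphere with per-trial annotations;
2. **preprocess**: resample to 500 Hz → line-noise notch → segmented-contact
   averaging → common average reference (CAR) per hemisphere → 1–50 Hz
   band-pass → onset-locked epochs on the fixed −2,000…+1,000 ms grid
   (1,501 samples at 2 ms);
3. **timefreq**: per-trial complex Morlet wavelet power (spectral-domain
   convolution), dB normalization against the whole-epoch baseline, trial and
   participant averaging;
4. **surrogate_stats**: shuffled-baseline surrogate null, two-tailed pixel
   thresholding at p < 0.001 (uncorrected) for single conditions and condition
   contrasts, evaluated over −500…+1,000 ms;
5. **bandpower_lme**: band × window mean dB power per
   participant/hemisphere/contact/task, linear mixed model with Type III
   Satterthwaite tests and Bonferroni follow-ups.

## The synthetic cohort generator

`synth_config()` fixes the study conditions: 13 participants × 2 hemispheres,
30 trials per task (protocols collect 30–50), raw sampling at 2,000 Hz,
trial durations drawn as truncated normals around 0.96 / 1.27 / 1.60 s
(vowel / DDK / sentence, SD 0.15 s — the SD is a free choice; the means match
typical median utterance durations for these tasks), and inter-trial intervals
as a truncated normal with mean 1.5 s, SD 0.6 s, bounds 0.8–3.1 s. Tasks are
scheduled in interleaved blocks of ten, as they are administered
intraoperatively.

Each channel carries an independent 1/f^α background (α = 1 by default,
spectral synthesis with the DC bin removed). Event-locked effects are injected
by scaling the channel's own band-passed component inside the trial window:

```{r}
y <- inject_modulation(x, 2000, band = c(1, 8), window_ms = c(0, 1000),
                       delta_db = +3, onsets_s = onsets)
```

adds `(10^(delta_db/20) − 1) ×` the 1–8 Hz component under a raised-cosine
envelope (50 ms ramps), so in-window band power changes by `delta_db` while
out-of-band and out-of-window power is untouched. Scaling the signal's own
band component — rather than adding an independent oscillation — is what makes
*negative* effects (beta desynchronization) possible at all: added independent
power can only increase variance. The band is isolated with a sharp
linear-phase FIR (Hamming design, transition ≈ max(1, low/4) Hz) because the
injected-versus-measured dB contract is only exact when the extraction filter
is near-ideal in its passband.

Default effect sizes are free parameters (field reports do not quantify the
effects in dB): during-speech theta +1 / +2.5 / +3 dB and prespeech beta
−0.5 / −1 / −2 dB for vowel / DDK / sentence, graded in the order the
experimental literature reports. Every injected effect is offset by a
participant-level `N(0, 0.5 dB)` draw, so the mixed model's random intercept
has real variance to estimate. Segmented (8-contact) leads receive identical
gains and timing on every segment over independent noise, so averaging
segments to contact depth preserves the effect while reducing noise.

What the generator deliberately does *not* emulate: tremor artifacts,
microphone cross-talk, volume conduction between contacts, non-stationary
background spectra, or behavioural variability in task performance. Passing
tests therefore demonstrate correctness of the analysis chain under the
model's assumptions, not robustness to every pathology of operating-room data.

## Preprocessing choices

* All filters are zero-phase (forward–backward), so perievent latencies are
  never biased. The band-pass is a Butterworth high-pass/low-pass cascade with
  corners placed at 0.75·low and 1.10·high: after the forward–backward pass
  the band edges themselves lose < 1 dB while one octave outside the band is
  attenuated > 20 dB. A direct 4th-order band-pass with a 1 Hz corner at
  500 Hz sampling is numerically fragile; the cascade is not.
* Line noise is removed by a biquad notch bank (zeros on the unit circle at
  each harmonic, 2 Hz bandwidth, applied forward–backward). Synthetic data
  carry no mains noise, so this stage is near-identity by default
  (`line_hz = NULL` skips it); the contract — ≥ 20 dB at the line frequency,
  < 0.5 dB elsewhere in 1–50 Hz — is what downstream stages rely on.
* Epoch grid: t = 0 is the sample nearest the onset; inclusive endpoints give
  1,501 samples. Epochs are cut independently, so with realistic intervals
  (onsets ~2.8 s apart, 3 s epochs) neighbouring trials share samples; that
  non-independence is accepted as a property of the design and handled in the
  statistics (below).
* Epochs also carry `guard_ms = 1700` of real recording context on each side.
  The wavelet stage convolves over the extended series and crops back to the
  grid, so no sample on the grid is contaminated by zero-padding; 1,700 ms
  covers the longest default kernel (3 cycles at 1 Hz spans ±1.67 s). Without
  the guard, edge attenuation leaks into the −500…+1,000 ms evaluation window
  for frequencies below ~3 Hz and biases both maps and their calibration.
* Segment averaging runs before CAR (segments are an acquisition detail;
  rereferencing operates on the four contact depths).

## Time–frequency decomposition and normalization

The wavelet bank spans 1–50 Hz with 50 logarithmically spaced frequencies
(the count is configurable; 50 gives ~26 bins in 1–8 Hz and ~11 in 13–30 Hz).
Cycle counts grow linearly in log-frequency from 3 at 1 Hz to 10 at 50 Hz.
Kernels are unit-energy complex Morlets truncated at ±3.5 temporal SDs; the
spectral path (FFT, multiply, inverse FFT, with zero-padding past the
wrap-around point) equals brute-force convolution to ≤ 1e−6 relative error,
which the test suite asserts against an independent O(n·k) implementation.
Amplitude-versus-energy kernel normalization is irrelevant downstream: the dB
step divides by a per-frequency baseline, cancelling any per-frequency gain.

Normalization is `dB = 10·log10(power_t / power_baseline)` with
`power_baseline` the mean linear power over the whole −2,000…+1,000 ms epoch,
computed per trial and frequency. Per-trial (rather than across-trial)
baselines are the default because single-trial power is heavily right-skewed
and the per-trial log-ratio is what is averaged into maps; the across-trial
alternative is available (`per_trial = FALSE`). Two identities pin the
implementation down: a constant-power trial maps to 0 dB everywhere, and the
mean of `10^(dB/10)` over the baseline window is exactly 1 per trial and
frequency.

## Surrogate significance

The null distribution for a map pixel is built from the baseline period
(−1,000, −500] ms (open on the left, closed on the right — 250 samples at
500 Hz). Each of 2,241 draws forms the same statistic as the observed map:
an average over trials (and, at group level, over participants) of baseline
dB values.

Three design decisions here deserve justification, because the obvious scheme
fails its own calibration:

1. **Trials are resampled, not held fixed.** Drawing only random baseline
   *times* for a fixed trial set underestimates the null spread wherever the
   wavelet's temporal smoothing exceeds the 500 ms baseline window (roughly
   below 8 Hz): within one trial, all baseline samples then move together, so
   time draws barely vary, while the observed pixel still fluctuates with the
   full trial-to-trial variance. Measured on effect-free cohorts, the plain
   time-shuffle rejects ~15% of pixels at α = 0.001.
2. **Trial resampling respects temporal dependence.** Because epochs overlap,
   power values of neighbouring trials at the same perievent latency are
   correlated at low frequencies. The null therefore uses a moving-block
   bootstrap (blocks of 5 chronologically consecutive trials, one shared
   baseline latency per block), which carries that covariance into the null
   where independent per-trial draws would understate it.
3. **Participants are resampled at group level.** The grand-average observed
   statistic varies across realizations with between-participant variance;
   averaging per-participant draws without resampling them leaves that
   component out of the null entirely, and slow background fluctuations that
   shift a whole participant between the baseline and evaluation windows then
   masquerade as effects. Each group draw therefore averages a
   with-replacement resample of the participants' draws (a hierarchical
   bootstrap).

With all three in place, the empirical per-pixel rejection rate on effect-free
cohorts (5 participants, 30 trials/task) stays well inside [0, 4α] at
α = 0.001, which both the test suite and `scripts/acceptance.R` measure. The
plain time-shuffle remains available (`resample_trials = FALSE`), as does an
independent-trial bootstrap (`block_len = 1`).

P-values use the add-one permutation convention,
`p = 2·min((1+#{≥obs}, 1+#{≤obs}))/(n+1)`, capped at 1, so p is never zero
and the smallest attainable two-tailed p at n = 2,241 is ≈ 8.9e−4 — still
below the α = 0.001 map threshold. Below n = 2,000 that resolution is lost
and `build_null()` warns; below 200 it refuses. No multiple-comparison
correction is applied to the maps (deliberately; the band-power mixed model
is the corrected, confirmatory stage). Between-condition contrasts subtract
unthresholded per-participant maps first and build the null from
per-participant differences of independent baseline draws, pooled with the
same participant resampling.

## Band power and the mixed model

Band × window means use delta/theta = 1–8 Hz and beta = 13–30 Hz (inclusive
bounds on the log-spaced axis) over prespeech [−500, 0) ms and during-speech
[0, 1,000] ms — the onset sample belongs to the during-speech window (the
half-open convention is a choice; nothing downstream is sensitive to one
2 ms column). For the full bilateral 13-participant design this yields
104 rows (2 × 4 × 13) per task for each band × window cell.

The model is `mean_power ~ task * laterality * contact + (1 | participant)`,
fitted by REML with sum-to-zero contrasts (required for meaningful Type III
tests), Type III F tests with Satterthwaite denominator degrees of freedom,
and Bonferroni-adjusted pairwise task contrasts (family of 3) as follow-ups;
when the task × laterality interaction is significant, simple-effect
contrasts within each level are added, each family adjusted at its own size.
A participant random intercept (rather than random slopes) matches the
classical balanced-design residual df: with 13 participants,
312 observations, 24 cell means and 12 participant contrasts, the task
effect's denominator df is 276, and the Satterthwaite value reproduces this
to < 0.5 on simulated balanced tables. Singular fits (participant variance
estimated at zero) are flagged, not hidden.

## Problem sizes used in validation

The test suite and the acceptance script run entirely on synthetic cohorts:
the structural checks on the full bilateral 13-participant design; surrogate
calibration on effect-free 5-participant cohorts (30 trials/task), pooling
one task per seed across seeds; effect recovery on one 5-participant cohort
with the default injected effects, with contrasts evaluated on contact 1
tensors pooled over both hemispheres; and the mixed-model detection rate on
20 simulated band-power tables at 5 participants (the table-level generator
draws cell means directly — task effect + participant offset + residual —
which is the regime the model addresses; running the full signal chain for
every replicate would add wavelet noise but no information about the model
stage). These sizes are the package's validation choices and are stated here
so they can be scaled up.

## Known limitations

* The surrogate test at frequencies below ~2 Hz has few effective degrees of
  freedom in a 500 ms baseline; even the hierarchical bootstrap leaves
  occasional cohort-level excursions in single realizations (the pooled rate
  stays within bounds). Interpreting isolated sub-2 Hz pixels in a single
  cohort remains inadvisable.
* Line-noise removal is a notch bank, adequate for stationary mains
  contamination; transient broadband artifacts are out of scope, and no
  amplitude- or ICA-based trial rejection is performed.
* EDF I/O is a minimal 16-bit implementation (continuous recordings, equal
  rates across channels) sufficient for exchanging synthetic sessions;
  obscure EDF+ features are not supported.
* The generator's effects are band-limited and time-locked by construction;
  real speech-related LFP dynamics (within-trial power drift, tremor
  harmonics, movement artifacts) are not modelled.
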