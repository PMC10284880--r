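---
title: "Measuring and modeling auditory-motor synchronization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and modeling auditory-motor synchronization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`audiomotor` studies how well people align rhythmic motor output -
whispering a syllable or clapping - with a quasi-regular auditory stimulus
whose tempo accelerates. This vignette explains the measurement model, the
synthetic-participant model, the statistical machinery, and the numerical
and design choices behind each, so that results produced by the package can
be interpreted (and distrusted) correctly.

## The task and its stimuli

A synchronization task presents a 50-s rhythmic train of acoustic units
whose presentation rate steps from 4.3 to 4.7 units/s in 0.1 units/s
increments, each rate held for 10 s (`make_rate_schedule()`). Onset times
within a plateau are spaced at exactly the reciprocal rate; the interval
straddling a plateau boundary is completed at the old rate and the new rate
applies from the next onset, so the rhythm's phase is continuous. Four unit
types are provided (`synth_stimulus()`):

* **tones** - a repeated 1 kHz carrier, amplitude-modulated by a triangular
  window that rises to its peak within one sample and decays linearly over
  150 ms: a pronounced attack.
* **speech** - 16 distinct consonant-vowel-like units in pseudo-random
  order with no immediate repetition, joined by a 20-ms equal-power
  crossfade that stands in for coarticulation. The built-in bank is
  synthetic (noise-burst consonant + two-formant vowel surrogate); a user
  bank of recorded syllable waveforms can be supplied instead. What matters
  for the scientific question is unit-identity variability and soft
  onsets, not the phonetics of a specific voice.
* **various tones** - 16 carriers logarithmically spaced on 0.5-2 kHz,
  pseudo-random order, amplitude following the positive half-waves of a
  sine at the plateau rate (soft onset and offset). The modulation phase is
  integrated through the schedule; with 10-s plateaus at 4.3-4.7 units/s
  every plateau contains a whole number of cycles, so this coincides with
  switching the sine frequency piecewise at the plateau boundaries (the
  boundary instants themselves carry zero amplitude either way, which
  resolves the ambiguity of defining the modulation by open intervals).
* **same tone** - the sine modulation applied to a single 1 kHz carrier.

`synth_surrogate()` builds the matching fixed-rate (default 4.3 units/s)
control audio from the same units. Synthesis defaults to 16 kHz; any rate
at or above 8 kHz is accepted. All synthesis is deterministic given
(schedule, bank, seed, sample rate).

The exact geometric frequency ladder for the various-tones bank is
`f_k = 0.5 * 4^(k/15)` kHz. Two entries of this ladder (1.2599 and
1.5157 kHz) are commonly quoted rounded down (1.25, 1.51); the package
always uses the exact geometric values.

## The synchrony measurement

Synchrony between a response recording and the stimulus is computed on the
amplitude envelopes of both:

1. **Envelope**: magnitude of the analytic signal (FFT-based Hilbert
   transform) of the full-band waveform - or full-wave rectification via
   `method = "rectify"` - smoothed by a zero-phase low-pass at 10 Hz and
   resampled onto a uniform 200 Hz grid. The low-pass is implemented in the
   frequency domain (raised-cosine transition centred on the cutoff)
   rather than as an IIR filter: a 10 Hz corner at a 16 kHz sampling rate
   has a normalized cutoff of 1.25e-3, where double-precision IIR
   realizations are numerically fragile, while the FFT realization is
   exactly zero-phase and unconditionally stable. Because the envelope is
   band-limited to 12 Hz before the 200 Hz grid is sampled, the
   resampling is alias-free.
2. **Band-pass**: zero-phase (forward-backward) Butterworth band-pass,
   3.3-5.7 Hz, bracketing the 4.3-4.7 units/s stimulation rates. The
   design is 2nd order per pass; two passes give a 4th-order effective
   magnitude response with exactly zero phase, so measured lags are not
   biased by filter delay. Attenuation one octave outside the band exceeds
   40 dB. (An 8-pole design showed passband ripple under
   forward-backward filtering in this narrow low band, which is why the
   4-pole realization is used.)
3. **Phase**: the angle of the analytic signal of the filtered envelope,
   wrapped to (-180, 180] degrees.
4. **PLV**: the phase-locking value over a window of `T` samples is the
   modulus of the mean unit phasor of the phase difference,
   `PLV = |sum e^{i(theta_stim - theta_resp)}| / T`, computed on 5-s
   windows sliding in 3-s steps (2-s overlap) anchored at the start of the
   common interval, trailing partial windows discarded; a 50-s task yields
   16 windows whose PLVs are averaged. For a 10-s training segment the
   same grid yields 2 windows - sham values are not directly comparable
   with task values in window count.
5. **Lag**: the circular mean of the pointwise phase difference (stimulus
   minus response) over the whole series, in degrees; positive lag means
   the stimulus event precedes the response. `phase_lag_to_ms()` converts
   through the cycle duration (about 222 ms at these rates).

Two null measurements accompany the experimental synchrony. *Sham
synchrony* (`sham_synchrony()`) scores the training recording - rhythm
produced with no concurrent audio - against the first 10 s of the
stimulus: the chance synchrony of an internally generated rhythm.
*Surrogate synchrony* (`surrogate_synchrony()`) scores the task response
against the fixed-rate audio: a responder genuinely tracking the
accelerating tempo scores lower against the surrogate than against the
true stimulus, a responder stuck near the base rate scores higher.

Conventions worth knowing: envelopes are resampled to 200 Hz first and
filtered second; stereo files are averaged to mono with a warning; the
absolute lag of a measured pair also reflects the morphology of the
response bursts relative to the stimulus units (burst shape shifts the
envelope's band-limited phase by a roughly constant offset), so *changes*
in lag - e.g. a delay added to the response - are recovered accurately
(within 5 degrees for 10-30 ms delays in the property tests) while
*absolute* lags should be compared only within a fixed rendering.

## The synthetic participant

The generator exists to produce cohorts with the population structure the
analysis module is designed to detect: a bimodal split between "high"
synchronizers, who couple to any rhythmic stimulus, and "low"
synchronizers, whose coupling collapses when the units' identity varies.

Each participant is a forced phase oscillator in the standard Kuramoto
form,

    dphi/dt = 2 pi f_nat + K sin(theta_stim - phi) + sigma dW,

emitting a motor event at every upward crossing of a multiple of 2 pi
(`simulate_oscillator()`, Euler-Maruyama on the 200 Hz stimulus-phase
grid). This is the minimal model consistent with the coupled-oscillator
account of the task: it locks when the coupling exceeds the detuning
`2 pi |f_stim - f_nat|`, settles at the phase-precession fixed point
`asin(2 pi df / K)` that grows as the external rate departs from the
internal one, and free-runs at `f_nat` when uncoupled. It is a modeling
choice, not an empirical claim.

Defaults (all per-participant parameters are jittered log-normally across
a cohort):

| parameter | vocal tract | hands | notes |
|---|---|---|---|
| natural rate, high group | 4.5 Hz | 2.0 Hz | tongue comfortable at 4-5 Hz; hands much slower |
| natural rate, low group | 3.8 Hz | 2.0 Hz | see below |
| coupling K (repeated units) | 15 rad/s | 22 rad/s | locks across the whole schedule |
| variable-identity multiplier (low group) | 0.15 | 0.15 | the single knob encoding the impairment |
| phase noise sigma | 2 rad/sqrt(s) | 2 | Wiener; participant CV 0.5 |
| onset jitter SD | 22 ms | 12 ms | Gaussian, truncated at 3 SD; participant CV 0.4 |
| anticipation | 50 ms | 0 | motor event precedes the phase crossing |
| articulatory delay | 50 ms | - | sound onset trails the motor event |

Three of these deserve justification:

* **Low-group vocal natural rate 3.8 Hz.** If low synchronizers'
  intrinsic rate sat inside the 4.3-4.7 Hz stimulation range, even the
  strongly reduced variable-unit coupling would eventually lock (zero
  detuning requires zero coupling to avoid locking), and shifting the rate
  by priming could not help. Placing the low group's intrinsic rate
  slightly below the range makes the impairment an interaction of weak
  coupling with detuning - and makes rhythmic priming (below) effective -
  which is the only configuration of this model family that reproduces
  both observations at once.
* **Anticipation.** Produced sound is scored, but the motor event is what
  the oscillator times. Whispered-syllable acoustics trail the articulatory
  gesture by roughly 50 ms, while the classic finding in synchronization
  tasks is that the motor event slightly *precedes* the beat. A 50 ms
  vocal anticipation cancels the articulatory delay, leaving vocal lags
  near the oscillator's fixed point, while clap lags express the large
  hands detuning - reproducing the ordering (hands lag > vocal lag)
  qualitatively.
* **Dispersion and session factors.** Between-participant spread (coupling
  CV 0.25, noise CV 0.5, jitter CV 0.4) is set so that within-group PLV
  SDs land near 0.1-0.15 per condition - the between-subject variability
  typical of this task - rather than the razor-thin spreads an idealized
  oscillator would produce. Each of the four conditions is treated as a
  separate session (the tasks are recorded hours apart) with its own
  log-normal motor-state factor (CV 0.3) scaling noise and jitter, which
  keeps the four PLV dimensions from being perfectly correlated within a
  participant.

Responses are rendered to audio (`render_response_audio()`): claps as
10-ms broadband noise transients, whispers as 120-ms noise bursts with
speech-band shaping and the articulatory delay. `simulate_participant()`
runs oscillator, rendering and the full measurement stack for the four
effector-by-stimulus conditions, plus sham (free-running training segment)
and surrogate measurements. `simulate_population()` assembles the default
cohort of 30 high and 21 low synchronizers, draws years of musical
training with a higher mean for highs (6 vs 3 years, SD 3, truncated at
zero) and assigns gender independently of group.

**Priming** (`simulate_priming()`): the speech-vocal task is rerun with
the oscillator's natural rate initialized at the facilitator stimulus's
end rate (4.7 Hz), relaxing exponentially back to baseline with a 120-s
time constant - longer than the 50-s task, so the shift mostly persists,
but is configurable; at a zero time constant active priming degenerates
exactly to baseline. Passive listening and baseline leave the rate
untouched. The open question of whether priming shifts the natural rate or
transiently raises coupling is resolved in favor of the rate shift (the
mechanism that interacts correctly with the low group's detuning); the
relaxation constant is the knob that expresses the instability of the
primed state.

What the generator does *not* emulate: real articulator acoustics,
amplitude dynamics of fatigue, tempo drift other than Wiener noise,
learning across sessions, and any gender difference in performance
(gender is a pure covariate). Passing tests on synthetic cohorts therefore
show that the analysis recovers the structure this model encodes - not
that real populations have it.

## Population analysis

`select_clusters_bic()` fits Gaussian finite mixtures (via mclust) to the
participants' 4-D PLV vectors for k = 1..5 and selects the k minimizing
BIC (`-2 log L + p log n`). PLVs are bounded on [0, 1] and pile up toward
the ceiling, so the mixture is fitted on the Fisher-z scale
(`atanh`) by default - the standard variance-stabilizing transform for
correlation-like quantities; a Gaussian mixture fitted to raw bounded
values tends to split skewed ceiling clumps into spurious components.
Inputs outside [0, 1] are fitted untransformed, and `transform = "none"`
forces raw-scale fitting. Columns are not standardized by default (all
four dimensions already share one scale). The cluster with the larger
mean PLV is labelled "high". `r_squared` is between-cluster over total
sum of squares of the original PLV vectors. A random-forest-proximity +
PAM mode (`method = "rf"`, k by average silhouette) is included for
comparison because tree-ensemble clustering is sometimes preferred for
mixed-scale synchrony data; it does not participate in BIC selection.

`rm_anova()` is the factorial workhorse: a repeated-measures ANOVA with
effector and stimulus as two-level within-subject factors and synchrony
group between subjects, optionally gender as a second between factor and
years of training as a covariate. It uses type-III sums of squares with
sum-to-zero contrasts (the group sizes are unbalanced) through the
multivariate-model route, reporting the univariate table - sphericity is
trivially satisfied with two-level factors. `posthoc_paired()` provides
the Bonferroni-corrected paired contrasts; `circular_group_compare()`
compares preferred phases between groups with a seeded permutation test on
the circular distance between group mean directions (the specific
published circular routine is unnamed, so a permutation construction is
used and calibrated under the null); `fisher_exact_2x2()` and
`independent_t()` cover the gender association and the training-years
comparison. All functions report exact p-values; thresholds are applied
downstream.

## Numerical choices and degenerate inputs

* Phase wrapping is (-180, 180]; ties at the boundary map to +180.
* Onset detection (`detect_onsets()`) is peak-picking on the smoothed
  envelope with a 30%-of-max threshold and 100-ms minimum separation;
  the measured rate of a plateau is the inverse mean inter-onset interval,
  which is insensitive to edge effects.
* Empty audio, empty phase segments, mismatched lengths, bands outside
  Nyquist, series shorter than one window, single-unit banks asked for
  repeat-free sequences, negative table counts and undersized samples all
  raise immediate, named errors rather than propagating NaNs.
* Zero-variance clustering input degrades to a single cluster with a
  warning; identical-sample circular comparisons are rejected as
  degenerate; zero-variance t contrasts return the appropriate limit
  (t = 0 or signed infinity).
* Every stochastic stage takes an explicit seed; cohort members derive
  independent child seeds from the master seed, so any single participant
  can be regenerated alone. RNG state of the caller is always restored.

## Problem sizes

Simulated cohorts default to 30 + 21 participants with audio rendered at
8 kHz (stimulus synthesis for external use defaults to 16 kHz; the
envelope analysis lives below 10 Hz, so the measurement chain is
unaffected by this choice). One full cohort - 204 recordings, each scored
against stimulus, sham and surrogate references - is a desk-scale
computation, and the package's own test suite runs cohorts across ten
seeds to check that two-cluster recovery, the group-by-stimulus and
group-by-effector patterns, and the sham/surrogate orderings are stable
properties rather than single-seed accidents.

## Known limitations

* Absolute phase lags include a rendering-morphology offset (see above);
  only lag differences are calibrated.
* The oscillator cannot produce genuine anticipatory tracking (negative
  asynchrony) mechanistically; anticipation is a constant offset.
* The built-in syllable bank is a synthetic surrogate; conclusions about
  specific phonetic material require user-supplied recordings.
* Gaussian-mixture BIC selection on 4-D data is only trustworthy for
  cohorts of a few dozen or more; below about 2 x k_max participants the
  function refuses to run.
* The sham measurement uses 2 windows and is accordingly noisy; treat
  individual sham values as baselines for paired contrasts, not as
  precise chance levels.
* Unsupervised recovery of group labels is not perfect on every cohort:
  with the default heterogeneity, a minority of simulated cohorts contain
  high synchronizers whose noise/jitter tail draws depress their
  speech-condition PLVs into the low group's range. These participants are
  misassigned by any two-component Gaussian posterior (while a supervised
  classifier given the true labels still separates the groups), and
  occasionally the BIC prefers a third component for them - the classic
  components-versus-clusters behavior of mixture BIC on skewed clusters.
  The package's tests quantify this directly; treat cluster labels near
  the group boundary as uncertain, exactly as one would with real data.
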