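# audiomotor

Tools for studying auditory-motor synchronization: how well rhythmic motor
output (whispered syllables, hand claps) aligns with a quasi-regular
auditory stimulus whose tempo accelerates. The package is aimed at
psychoacoustics and speech-motor researchers who need the complete chain —
stimulus synthesis, synchrony measurement, synthetic cohorts, and
population statistics — reproducible from a single seed.

The population of interest splits into two groups: *high synchronizers*,
who entrain to any rhythmic sequence, and *low synchronizers*, whose
synchrony collapses when the acoustic unit's identity varies across the
sequence (different syllables or tones) and is restored when a single unit
repeats. The package synthesizes the four stimulus types that probe this
(repeated sharp-attack tones, variable syllable-like units, 16
sine-modulated tones, one sine-modulated tone), measures synchrony, and
runs the clustering and factorial statistics that separate the groups.

## The measurement

Synchrony between stimulus and response is the windowed phase-locking
value of their amplitude-envelope phases:

    PLV = (1/T) | Σ_t exp{ i (θ₁(t) − θ₂(t)) } |

where θ₁, θ₂ are instantaneous Hilbert phases of the two envelopes,
resampled at 200 Hz and band-passed 3.3–5.7 Hz around the 4.3–4.7 units/s
presentation rates, and T spans a 5-s window; windows slide in 3-s steps
(2-s overlap) and their PLVs are averaged. The circular mean of θ₁ − θ₂
(stimulus minus response) is the phase lag: positive means the stimulus
precedes the response, and `phase_lag_to_ms()` converts through the
≈222 ms cycle. Sham synchrony (training production with no audio vs. the
stimulus opening) and surrogate synchrony (task response vs. fixed-rate
audio) provide the null comparisons.

Simulated participants are forced Kuramoto phase oscillators,
dφ/dt = 2π·f_nat + K·sin(θ_stim − φ) + noise, whose events are rendered
to clap- or whisper-like audio and scored by the same measurement stack.
Cluster number is selected by BIC over Gaussian mixtures on each
participant's 4-D PLV vector; a repeated-measures ANOVA (effector ×
stimulus within, group between) with Bonferroni post-hocs, a circular
permutation test, Fisher's exact test and t contrasts cover the
population-level questions.

## Worked example

```r
library(audiomotor)

sched <- make_rate_schedule(4.3, 4.7, 0.1, 10)
sched
#> Rate schedule: 5 plateau(s), 50 s total
#>   rates 4.3, 4.4, 4.5, 4.6, 4.7 units/s, 10 s each

stim <- synth_stimulus("tones", sched, sample_rate = 16000)
stim
#> Audio track: 50 s, 16000 Hz (800000 samples), peak 1.000
```

Score a response against the stimulus — here the response is the stimulus
itself delayed by 20 ms, so phase locking is perfect and the lag is the
delay plus the (constant) offset of the measurement chain:

```r
resp <- audio_track(c(numeric(320), stim$samples[1:(800000 - 320)]), 16000)
measure_sync(resp, stim)
#> Synchrony: mean PLV 1.000 over 16 windows; mean lag +32.4 deg
phase_lag_to_ms(32.4, 222.2)
#> [1] 20.0
```

The mean PLV of 1.000 over 16 windows says the phase relation never
drifts; the +32.4° lag is the injected 20 ms expressed in phase at the
≈4.5 Hz rhythm.

Simulate a small cohort and recover its group structure:

```r
coh <- simulate_population(n_high = 10, n_low = 7, seed = 42)
summary(coh)
#> Mean PLV by true group and condition:
#>   group plv_speech_vt plv_speech_hands plv_tones_vt plv_tones_hands
#> 1  high         0.830            0.868        0.845           0.896
#> 2   low         0.274            0.324        0.851           0.869

select_clusters_bic(coh)
#> Cluster solution (gmm): 2 cluster(s), R^2 = 0.675
#> BIC by k (minimized):
#>     1     2     3     4     5
#> 140.2 124.7 131.1 139.5 147.9
#> Cluster sizes: 8, 9
```

The low group synchronizes to tones (~0.85) but not to the syllable train
(~0.3), while the high group synchronizes to both — and the BIC curve
bottoms out at two clusters. `rm_anova(coh)` then quantifies the
group-by-stimulus interaction, and `run_demo()` executes the whole chain
(stimuli → cohort → measurement → clustering → ANOVA) and writes the
population CSV, effects CSV, cluster JSON and a provenance record.

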