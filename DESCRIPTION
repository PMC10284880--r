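Package: audiomotor
Title: Auditory-Motor Synchronization Analysis with Phase-Locking Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how well rhythmic motor output (whispered
    syllables, hand claps) synchronizes to quasi-regular auditory stimuli.
    Synthesizes accelerating rhythmic stimulus trains (repeated tones,
    sine-modulated tone sequences, syllable-like unit trains) and fixed-rate
    surrogate audio; measures stimulus-response synchrony as windowed
    phase-locking values and circular phase lags of band-limited Hilbert
    envelope phases, with sham and surrogate nulls; simulates stimulus-coupled
    phase-oscillator participants and full cohorts with a bimodal high/low
    synchronizer structure; and runs the population-level analyses that
    separate the groups (Gaussian-mixture cluster-number selection by BIC,
    repeated-measures factorial ANOVA with post-hoc paired contrasts,
    circular permutation tests, Fisher's exact test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    mclust,
    car,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    cluster
Config/testthat/edition: 3
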