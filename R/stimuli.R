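#' Banks of acoustic units
#'
#' A unit bank holds the acoustic units concatenated into a rhythmic train.
#' Three kinds are supported: `tone` (a single repeated carrier),
#' `variable_tone` (16 carriers logarithmically spaced on 0.5-2 kHz), and
#' `syllable` (consonant-vowel-like units; either user-supplied waveforms or
#' the built-in synthetic bank).
#'
#' @param kind one of `"tone"`, `"variable_tone"`, `"syllable"`.
#' @param units for `kind = "syllable"`, an optional named list of numeric
#'   waveforms (one per syllable, all at `sample_rate`); `NULL` uses the
#'   built-in synthetic bank of 16 units.
#' @param carrier_freq carrier frequency in Hz for `kind = "tone"`.
#' @param n number of units for `kind = "variable_tone"`.
#' @param sample_rate sample rate of supplied waveforms, Hz.
#' @return an object of class `unit_bank` with fields `kind`, `labels` and
#'   kind-specific parameters.
#' @examples
#' unit_bank("variable_tone")$freqs # 16 frequencies in Hz
#' @export
unit_bank <- function(kind = c("tone", "variable_tone", "syllable"),
                      units = NULL, carrier_freq = 1000, n = 16,
                      sample_rate = 16000) {
  kind <- match.arg(kind)
  out <- switch(kind,
    tone = list(kind = kind, labels = "tone", carrier_freq = carrier_freq),
    variable_tone = {
      freqs <- 1000 * log_spaced_freqs(0.5, 2, n)
      list(kind = kind, labels = sprintf("t%02d", seq_len(n)), freqs = freqs)
    },
    syllable = {
      if (is.null(units)) {
        labels <- builtin_syllable_labels()
        list(kind = kind, labels = labels, units = NULL,
             sample_rate = sample_rate, builtin = TRUE)
      } else {
        if (is.null(names(units)) || any(names(units) == ""))
          stop_invalid("supplied syllable units must be a named list")
        if (!all(vapply(units, is.numeric, TRUE)))
          stop_invalid("syllable unit waveforms must be numeric vectors")
        list(kind = kind, labels = names(units), units = units,
             sample_rate = sample_rate, builtin = FALSE)
      }
    })
  structure(out, class = "unit_bank")
}

#' @export
print.unit_bank <- function(x, ...) {
  cat(sprintf("Unit bank: kind '%s', %d unit(s)\n", x$kind, length(x$labels)))
  invisible(x)
}

builtin_syllable_labels <- function() {
  cons <- c("t", "p", "k", "s")
  vows <- c("a", "e", "i", "o")
  as.vector(outer(cons, vows, paste0))
}

# Synthetic consonant-vowel unit: a short noise burst (plosive/fricative
# surrogate) followed by a two-formant vowel surrogate with decaying
# amplitude. Deterministic given (label, sample_rate). These are stand-ins
# for recorded/synthesized syllables: they carry the acoustic properties the
# pipeline depends on (distinct unit identity, soft coarticulated onsets at
# the train level), not Spanish phonetics.
synth_cv_unit <- function(label, duration, sample_rate) {
  cons <- substr(label, 1, 1)
  vow <- substr(label, 2, 2)
  n <- max(1L, round(duration * sample_rate))
  t <- (seq_len(n) - 1L) / sample_rate
  # consonant: 25 ms noise burst, spectral center by consonant identity
  burst_len <- min(n, round(0.025 * sample_rate))
  f_burst <- c(t = 3500, p = 1200, k = 2200, s = 5000)[[cons]]
  seed <- sum(utf8ToInt(label)) * 131L + as.integer(sample_rate %% 1000L)
  noise <- with_seed(seed, stats::rnorm(burst_len))
  tb <- (seq_len(burst_len) - 1L) / sample_rate
  burst <- noise * sin(2 * pi * min(f_burst, 0.45 * sample_rate) * tb)
  burst <- burst * exp(-tb / 0.008)
  # vowel: two formant surrogates, amplitude decaying over the unit
  ff <- switch(vow,
               a = c(700, 1200), e = c(450, 1900),
               i = c(300, 2300), o = c(450, 850))
  ff <- pmin(ff, 0.45 * sample_rate)
  vowel <- 0.8 * sin(2 * pi * ff[1] * t) + 0.5 * sin(2 * pi * ff[2] * t)
  env <- exp(-t / (0.45 * duration)) * (1 - exp(-t / 0.01))
  x <- vowel * env
  x[seq_len(burst_len)] <- x[seq_len(burst_len)] + 0.9 * burst / max(abs(burst))
  x / max(abs(x))
}

#' Pseudo-random unit sequence without immediate repeats
#'
#' Draws a sequence of unit labels in which the same label never occurs
#' twice in a row, the concatenation rule for the syllable and
#' variable-tone stimuli.
#'
#' @param bank a [unit_bank()] (or a character vector of labels).
#' @param n_units length of the sequence.
#' @param seed RNG seed (reproducible draws).
#' @return character vector of length `n_units` with no adjacent repeats.
#' @export
sample_unit_sequence <- function(bank, n_units, seed = 1) {
  labels <- if (inherits(bank, "unit_bank")) bank$labels else as.character(bank)
  if (length(labels) < 2 && n_units > 1)
    stop_invalid("cannot build a repeat-free sequence from fewer than 2 units")
  if (n_units < 1) return(character(0))
  with_seed(seed, {
    seq_out <- character(n_units)
    seq_out[1] <- sample(labels, 1)
    for (k in seq_len(n_units)[-1]) {
      pool <- setdiff(labels, seq_out[k - 1])
      seq_out[k] <- if (length(pool) == 1L) pool else sample(pool, 1)
    }
    seq_out
  })
}

#' Synthesize the repeated-tone train
#'
#' Each unit is a carrier sinusoid whose amplitude rises instantaneously to
#' its peak at the unit onset and decays linearly over `fall_time`
#' (triangular modulation with a pronounced attack); silence fills the rest
#' of the inter-onset interval. Default carrier 1 kHz, fall time 150 ms.
#'
#' @param schedule a [make_rate_schedule()] object.
#' @param carrier_freq carrier frequency, Hz.
#' @param fall_time linear decay time of each unit, s.
#' @param sample_rate output sample rate, Hz (>= 2 x carrier).
#' @return an [audio_track()] of the schedule's total duration.
#' @export
synth_tone_train <- function(schedule, carrier_freq = 1000, fall_time = 0.15,
                             sample_rate = 16000) {
  stopifnot(inherits(schedule, "rate_schedule"))
  check_scalar(carrier_freq, "carrier_freq")
  check_scalar(fall_time, "fall_time")
  if (sample_rate < 2 * carrier_freq)
    stop_invalid("sample_rate must be at least twice the carrier frequency")
  total <- schedule_duration(schedule)
  n <- round(total * sample_rate)
  if (n == 0) return(audio_track(numeric(0), sample_rate))
  env <- numeric(n)
  onsets <- unit_onset_times(schedule)
  bounds <- c(onsets[-1], total)
  for (k in seq_along(onsets)) {
    i0 <- floor(onsets[k] * sample_rate) + 1
    i1 <- min(n, ceiling(min(onsets[k] + fall_time, bounds[k]) * sample_rate))
    if (i1 < i0) next
    tt <- ((i0:i1) - 1) / sample_rate - onsets[k]
    env[i0:i1] <- pmax(0, pmin(1, 1 - tt / fall_time))
  }
  t <- (seq_len(n) - 1) / sample_rate
  audio_track(env * sin(2 * pi * carrier_freq * t), sample_rate)
}

#' Synthesize a sine-modulated tone train
#'
#' Unit amplitudes follow the positive half-waves of a sine whose frequency
#' equals the plateau's unit rate, giving soft onsets and offsets. The
#' modulation phase is integrated through the schedule, which with 10-s
#' plateaus at 4.3-4.7 units/s is identical to switching the sine frequency
#' piecewise at the plateau boundaries (each plateau holds a whole number of
#' cycles). Each unit carries one frequency from `freqs`; a single frequency
#' gives the repeated same-tone stimulus, a repeat-free draw from the
#' variable-tone bank gives the 16-different-tones stimulus.
#'
#' @param schedule a [make_rate_schedule()] object.
#' @param freqs carrier frequency per unit, Hz: either a single value or a
#'   vector of length >= the number of units in the schedule.
#' @param sample_rate output sample rate, Hz.
#' @return an [audio_track()].
#' @export
synth_sine_train <- function(schedule, freqs = 1000, sample_rate = 16000) {
  stopifnot(inherits(schedule, "rate_schedule"))
  total <- schedule_duration(schedule)
  n <- round(total * sample_rate)
  if (n == 0) return(audio_track(numeric(0), sample_rate))
  if (sample_rate < 2 * max(freqs))
    stop_invalid("sample_rate must be at least twice the highest carrier")
  t <- (seq_len(n) - 1) / sample_rate
  ends <- cumsum(schedule$duration)
  starts <- c(0, ends[-length(ends)])
  phase_at_start <- 2 * pi * cumsum(c(0, schedule$rate * schedule$duration))
  plateau <- findInterval(t, starts, rightmost.closed = FALSE)
  psi <- phase_at_start[plateau] +
    2 * pi * schedule$rate[plateau] * (t - starts[plateau])
  env <- pmax(0, sin(psi))
  unit_idx <- floor(psi / (2 * pi)) + 1
  n_units <- max(unit_idx)
  if (length(freqs) == 1L) {
    freqs <- rep(freqs, n_units)
  } else if (length(freqs) < n_units) {
    stop_invalid("freqs must have length >= number of units (", n_units, ")")
  }
  f_unit <- freqs[unit_idx]
  # carrier phase restarts at each unit's modulation zero
  unit_start_t <- starts[plateau] +
    (unit_idx - 1 - phase_at_start[plateau] / (2 * pi)) / schedule$rate[plateau]
  carrier <- sin(2 * pi * f_unit * (t - unit_start_t))
  audio_track(env * carrier, sample_rate)
}

#' Synthesize a syllable-like unit train
#'
#' Draws a repeat-free unit sequence from the bank and concatenates the unit
#' waveforms at the schedule's onset times, joining consecutive units with a
#' short equal-power crossfade as a surrogate for coarticulation (soft
#' transitions between units).
#'
#' @param schedule a [make_rate_schedule()] object.
#' @param bank a syllable [unit_bank()]; the built-in synthetic bank by
#'   default.
#' @param seed RNG seed for the unit sequence.
#' @param sample_rate output sample rate, Hz.
#' @param crossfade crossfade length between consecutive units, s.
#' @return an [audio_track()].
#' @export
synth_syllable_train <- function(schedule, bank = unit_bank("syllable"),
                                 seed = 1, sample_rate = 16000,
                                 crossfade = 0.02) {
  stopifnot(inherits(schedule, "rate_schedule"))
  if (!inherits(bank, "unit_bank") || bank$kind != "syllable")
    stop_invalid("bank must be a syllable unit_bank")
  total <- schedule_duration(schedule)
  n <- round(total * sample_rate)
  if (n == 0) return(audio_track(numeric(0), sample_rate))
  onsets <- unit_onset_times(schedule)
  labs <- sample_unit_sequence(bank, length(onsets), seed = seed)
  slot_ends <- c(onsets[-1], total)
  nf <- round(crossfade * sample_rate)
  x <- numeric(n)
  for (k in seq_along(onsets)) {
    dur_k <- slot_ends[k] - onsets[k] + crossfade
    if (isTRUE(bank$builtin)) {
      w <- synth_cv_unit(labs[k], dur_k, sample_rate)
    } else {
      w <- bank$units[[labs[k]]]
      if (is.null(w)) stop_invalid("missing waveform for unit '", labs[k], "'")
      need <- round(dur_k * sample_rate)
      w <- if (length(w) >= need) w[seq_len(need)] else c(w, numeric(need - length(w)))
    }
    m <- length(w)
    if (m == 0) next
    # equal-power crossfade ramps at both ends (except track edges)
    ramp <- if (nf > 0) sin(seq(0, pi / 2, length.out = nf))^2 else numeric(0)
    if (k > 1 && nf > 0 && m > nf) w[seq_len(nf)] <- w[seq_len(nf)] * ramp
    if (k < length(onsets) && nf > 0 && m > nf)
      w[(m - nf + 1):m] <- w[(m - nf + 1):m] * rev(ramp)
    i0 <- floor(onsets[k] * sample_rate) + 1
    i1 <- min(n, i0 + m - 1)
    x[i0:i1] <- x[i0:i1] + w[seq_len(i1 - i0 + 1)]
  }
  peak <- max(abs(x))
  if (peak > 1) x <- x / peak
  audio_track(x, sample_rate)
}

#' Fixed-rate surrogate audio
#'
#' Builds an audio file made of the same acoustic units as an experimental
#' stimulus but concatenated at one constant rate (default 4.3 units/s) for
#' the full duration. Synchrony against this track tests whether a responder
#' follows the accelerating tempo rather than a fixed one.
#'
#' @param type stimulus type: `"tones"`, `"speech"`, `"various_tones"` or
#'   `"same_tone"`.
#' @param rate constant unit rate, units/s.
#' @param duration total duration, s.
#' @param seed RNG seed for unit order (variable-identity stimuli).
#' @param sample_rate output sample rate, Hz.
#' @param bank optional syllable [unit_bank()] for `type = "speech"`.
#' @return an [audio_track()].
#' @export
synth_surrogate <- function(type = c("tones", "speech", "various_tones",
                                     "same_tone"),
                            rate = 4.3, duration = 50, seed = 1,
                            sample_rate = 16000, bank = NULL) {
  type <- match.arg(type)
  check_scalar(rate, "rate")
  check_scalar(duration, "duration")
  sched <- structure(data.frame(rate = rate, duration = duration),
                     total_duration = duration,
                     class = c("rate_schedule", "data.frame"))
  synth_stimulus(type, schedule = sched, seed = seed,
                 sample_rate = sample_rate, bank = bank)
}

#' Synthesize any of the four experimental stimuli
#'
#' Convenience dispatcher over [synth_tone_train()], [synth_sine_train()] and
#' [synth_syllable_train()]:
#' \describe{
#'   \item{`tones`}{repeated 1 kHz tone, triangular 150 ms fall (sharp attack).}
#'   \item{`speech`}{16 syllable-like units, pseudo-random order, coarticulated.}
#'   \item{`various_tones`}{16 log-spaced tones (0.5-2 kHz), sine modulation.}
#'   \item{`same_tone`}{repeated 1 kHz tone, sine modulation (soft onsets).}
#' }
#'
#' @param type stimulus type.
#' @param schedule a [make_rate_schedule()]; the default accelerating
#'   4.3-4.7 units/s schedule if `NULL`.
#' @param seed RNG seed for unit order where applicable.
#' @param sample_rate output sample rate, Hz.
#' @param bank optional syllable [unit_bank()] for `type = "speech"`.
#' @return an [audio_track()].
#' @examples
#' stim <- synth_stimulus("tones")
#' stim$duration # 50
#' @export
synth_stimulus <- function(type = c("tones", "speech", "various_tones",
                                    "same_tone"),
                           schedule = NULL, seed = 1, sample_rate = 16000,
                           bank = NULL) {
  type <- match.arg(type)
  if (is.null(schedule)) schedule <- make_rate_schedule()
  switch(type,
    tones = synth_tone_train(schedule, sample_rate = sample_rate),
    same_tone = synth_sine_train(schedule, freqs = 1000,
                                 sample_rate = sample_rate),
    various_tones = {
      vb <- unit_bank("variable_tone")
      n_units <- length(unit_onset_times(schedule))
      labs <- sample_unit_sequence(vb, n_units, seed = seed)
      freqs <- vb$freqs[match(labs, vb$labels)]
      synth_sine_train(schedule, freqs = freqs, sample_rate = sample_rate)
    },
    speech = {
      if (is.null(bank)) bank <- unit_bank("syllable")
      synth_syllable_train(schedule, bank, seed = seed,
                           sample_rate = sample_rate)
    })
}
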