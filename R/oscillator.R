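#' Parameters of the motor phase oscillator
#'
#' The simulated participant is a forced phase oscillator (Kuramoto form):
#' `dphi/dt = 2*pi*natural_rate + coupling * sin(theta_stim - phi) + noise`,
#' emitting a motor event each time `phi` crosses a multiple of `2*pi`.
#' With zero coupling it free-runs at `natural_rate`; with coupling above
#' the detuning `2*pi*|f_stim - natural_rate|` it phase-locks with a
#' stationary lag `asin(2*pi*detuning/coupling)` (phase precession grows as
#' the external rate departs from the internal one).
#'
#' @param natural_rate intrinsic motor rate, Hz (the synchronizable range is
#'   roughly 0.5-7 Hz).
#' @param coupling coupling strength to the stimulus phase, rad/s (>= 0).
#' @param phase_noise Wiener phase-noise intensity, rad/sqrt(s).
#' @param onset_jitter SD of Gaussian timing jitter added to each motor
#'   event, s (truncated at +/- 3 SD).
#' @param initial_phase oscillator phase at t = 0, rad.
#' @return an `oscillator_params` list.
#' @export
oscillator_params <- function(natural_rate = 4.5, coupling = 15,
                              phase_noise = 1.5, onset_jitter = 0.01,
                              initial_phase = 0) {
  vals <- c(natural_rate, coupling, phase_noise, onset_jitter, initial_phase)
  if (!all(is.finite(vals)))
    stop_invalid("oscillator parameters must be finite")
  if (coupling < 0 || phase_noise < 0 || onset_jitter < 0)
    stop_invalid("coupling, phase_noise and onset_jitter must be >= 0")
  structure(list(natural_rate = natural_rate, coupling = coupling,
                 phase_noise = phase_noise, onset_jitter = onset_jitter,
                 initial_phase = initial_phase),
            class = "oscillator_params")
}

#' Integrate the stimulus-coupled motor oscillator
#'
#' Euler-Maruyama integration of the forced phase oscillator on the
#' stimulus phase grid; motor event times are the (linearly interpolated)
#' crossings of `2*pi` multiples, with optional Gaussian onset jitter.
#'
#' @param stimulus_phase a `phase_series` covering the task (e.g. from
#'   [as_stim_phase()] applied to a stimulus), or `NULL` for a free-running
#'   oscillator (coupling ignored).
#' @param params an [oscillator_params()].
#' @param duration task duration, s; defaults to the stimulus phase span.
#' @param seed RNG seed (noise and jitter are reproducible).
#' @param rate integration grid rate when `stimulus_phase` is `NULL`, Hz.
#' @param natural_rate_t optional vector of instantaneous natural rates on
#'   the integration grid (overrides the scalar; used for priming
#'   relaxation).
#' @return increasing vector of motor event times, s.
#' @export
simulate_oscillator <- function(stimulus_phase, params, duration = NULL,
                                seed = 1, rate = 200, natural_rate_t = NULL) {
  stopifnot(inherits(params, "oscillator_params"))
  if (!is.null(stimulus_phase)) {
    stopifnot(inherits(stimulus_phase, "phase_series"))
    theta <- stimulus_phase$phases
    rate <- stimulus_phase$rate
    n <- length(theta)
    if (!is.null(duration)) n <- min(n, round(duration * rate))
  } else {
    if (is.null(duration)) stop_invalid("duration required without a stimulus")
    n <- round(duration * rate)
    theta <- NULL
  }
  dt <- 1 / rate
  fn <- if (is.null(natural_rate_t)) rep(params$natural_rate, n)
        else rep_len(natural_rate_t, n)
  with_seed(seed, {
    noise <- if (params$phase_noise > 0)
      stats::rnorm(n, sd = params$phase_noise * sqrt(dt)) else numeric(n)
    phi <- numeric(n)
    phi[1] <- params$initial_phase
    K <- params$coupling
    for (k in seq_len(n - 1L)) {
      pull <- if (!is.null(theta) && K > 0) K * sin(theta[k] - phi[k]) else 0
      phi[k + 1] <- phi[k] + dt * (2 * pi * fn[k] + pull) + noise[k]
    }
    wraps <- floor(phi / (2 * pi))
    cross <- which(diff(wraps) >= 1)
    if (length(cross) == 0) return(numeric(0))
    # linear interpolation of the crossing instant within the step
    targets <- 2 * pi * wraps[cross + 1L]
    frac <- (targets - phi[cross]) / (phi[cross + 1L] - phi[cross])
    events <- (cross - 1L + pmin(pmax(frac, 0), 1)) * dt
    if (params$onset_jitter > 0) {
      j <- stats::rnorm(length(events), sd = params$onset_jitter)
      j <- pmin(pmax(j, -3 * params$onset_jitter), 3 * params$onset_jitter)
      events <- sort(events + j)
      events <- events[events >= 0]
    }
    events
  })
}

#' Render motor events as response audio
#'
#' Emulates the recorded sounds of the two effectors. Claps are short
#' (~10 ms) broadband noise transients at the event times. Whispered
#' syllables ("tah"-like) are ~120 ms noise bursts band-shaped to a
#' speech-like region, whose acoustic onset trails the motor event by an
#' articulatory delay (default 50 ms: the occlusion release follows tongue
#' contact by about that much).
#'
#' @param event_times increasing motor event times, s.
#' @param effector `"vocal_tract"` or `"hands"`.
#' @param duration output duration, s.
#' @param sample_rate output sample rate, Hz.
#' @param seed RNG seed for the noise carriers.
#' @param articulatory_delay sound onset delay after the motor event for the
#'   vocal tract, s.
#' @return an [audio_track()].
#' @export
render_response_audio <- function(event_times, effector = c("vocal_tract",
                                                            "hands"),
                                  duration = NULL, sample_rate = 8000,
                                  seed = 1, articulatory_delay = 0.05) {
  effector <- match.arg(effector)
  if (is.null(duration))
    duration <- if (length(event_times)) max(event_times) + 0.3 else 0
  n <- round(duration * sample_rate)
  x <- numeric(n)
  if (n == 0L || length(event_times) == 0L)
    return(audio_track(x, sample_rate))
  if (is.unsorted(event_times)) stop_invalid("event times must be increasing")
  if (effector == "hands") {
    burst_dur <- 0.01; delay <- 0; decay <- 0.003
  } else {
    burst_dur <- 0.12; delay <- articulatory_delay; decay <- 0.04
  }
  m <- round(burst_dur * sample_rate)
  tb <- (seq_len(m) - 1) / sample_rate
  env <- (1 - exp(-tb / 0.002)) * exp(-tb / decay)
  with_seed(seed, {
    for (ev in event_times) {
      i0 <- floor((ev + delay) * sample_rate) + 1
      if (i0 > n) next
      i1 <- min(n, i0 + m - 1L)
      len <- i1 - i0 + 1L
      carrier <- stats::rnorm(len)
      if (effector == "vocal_tract") {
        # crude speech-band shaping: difference of lagged noise
        carrier <- carrier + 0.7 * c(0, carrier[-len])
      }
      x[i0:i1] <- x[i0:i1] + env[seq_len(len)] * carrier
    }
    peak <- max(abs(x))
    if (peak > 0) x <- 0.9 * x / peak
    audio_track(x, sample_rate)
  })
}
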