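# Analytic signal (Hilbert transform) via the FFT construction.
analytic_signal <- function(x) {
  n <- length(x)
  if (n == 0L) return(complex(0))
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    if (n > 2) h[2:(n / 2)] <- 2
  } else if (n > 1) {
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Zero-phase FFT-domain low-pass with a raised-cosine transition band.
# Stable at any sample rate (an IIR low-pass at 10 Hz on 16 kHz audio is
# numerically fragile); exactly zero phase by construction.
fft_lowpass <- function(x, sample_rate, cutoff, transition = 0.4 * cutoff) {
  n <- length(x)
  if (n < 4L) return(x)
  f <- seq(0, sample_rate * (n - 1) / n, length.out = n)
  f <- pmin(f, sample_rate - f) # two-sided frequency axis
  gain <- rep(1, n)
  lo <- cutoff - transition / 2
  hi <- cutoff + transition / 2
  mid <- f > lo & f < hi
  gain[f >= hi] <- 0
  gain[mid] <- 0.5 * (1 + cos(pi * (f[mid] - lo) / (hi - lo)))
  Re(stats::fft(stats::fft(x) * gain, inverse = TRUE) / n)
}

envelope_series <- function(values, rate, t0 = 0) {
  structure(list(values = values, rate = rate, t0 = t0),
            class = "envelope_series")
}

phase_series <- function(phases, rate, t0 = 0) {
  structure(list(phases = phases, rate = rate, t0 = t0),
            class = "phase_series")
}

#' @export
print.envelope_series <- function(x, ...) {
  cat(sprintf("Envelope series: %d points at %g Hz (%.4g s)\n",
              length(x$values), x$rate, length(x$values) / x$rate))
  invisible(x)
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("Phase series: %d points at %g Hz (%.4g s)\n",
              length(x$phases), x$rate, length(x$phases) / x$rate))
  invisible(x)
}

#' Amplitude envelope of an audio track
#'
#' Tracks the slowly varying amplitude of a waveform: magnitude of the
#' analytic signal (or full-wave rectification), smoothed by a zero-phase
#' low-pass at `smooth_cutoff`, then resampled onto a uniform grid at
#' `target_rate` (default 200 Hz). The smoothing cutoff sits well above the
#' 3.3-5.7 Hz analysis band and well below `target_rate/2`, so decimation is
#' alias-free.
#'
#' @param audio an [audio_track()].
#' @param target_rate envelope sampling rate, Hz.
#' @param method `"analytic"` (default) or `"rectify"`.
#' @param smooth_cutoff low-pass cutoff applied before resampling, Hz.
#' @return an `envelope_series` with `length = round(duration * target_rate)`
#'   non-negative values.
#' @export
compute_envelope <- function(audio, target_rate = 200,
                             method = c("analytic", "rectify"),
                             smooth_cutoff = 10) {
  stopifnot(inherits(audio, "audio_track"))
  method <- match.arg(method)
  if (length(audio$samples) == 0L)
    stop_invalid("cannot compute the envelope of empty audio")
  if (target_rate <= 2 * smooth_cutoff)
    stop_invalid("target_rate must exceed twice the smoothing cutoff")
  x <- audio$samples
  env <- switch(method,
                analytic = Mod(analytic_signal(x)),
                rectify = abs(x))
  env <- fft_lowpass(env, audio$sample_rate, smooth_cutoff)
  env[env < 0] <- 0 # low-pass ringing can cross zero slightly
  n_out <- round(audio$duration * target_rate)
  t_in <- (seq_along(env) - 1) / audio$sample_rate
  t_out <- (seq_len(n_out) - 1) / target_rate
  vals <- stats::approx(t_in, env, xout = pmin(t_out, max(t_in)))$y
  envelope_series(vals, target_rate)
}

#' Band-pass filter an envelope around the stimulation rates
#'
#' Zero-phase (forward-backward) Butterworth band-pass, default band
#' 3.3-5.7 Hz around the 4.3-4.7 units/s presentation rates. Two passes of
#' the 2nd-order design give a 4th-order effective magnitude response with
#' no phase distortion, so phase lags are not biased by filter delay.
#'
#' @param env an `envelope_series`.
#' @param lo,hi band edges, Hz (`0 < lo < hi < rate/2`).
#' @param order Butterworth design order per pass.
#' @return a filtered `envelope_series` (values may be negative).
#' @export
bandpass <- function(env, lo = 3.3, hi = 5.7, order = 2) {
  stopifnot(inherits(env, "envelope_series"))
  if (!(0 < lo && lo < hi && hi < env$rate / 2))
    stop_invalid("band edges must satisfy 0 < lo < hi < rate/2")
  if (length(env$values) < 12 * order)
    stop_invalid("envelope too short to band-pass filter")
  bf <- signal::butter(order, c(lo, hi) / (env$rate / 2), type = "pass")
  vals <- signal::filtfilt(bf, env$values - mean(env$values))
  envelope_series(vals, env$rate, env$t0)
}

#' Instantaneous phase of a band-limited envelope
#'
#' Angle of the analytic signal, wrapped to `(-pi, pi]`. Meaningful for
#' band-limited input (apply [bandpass()] first).
#'
#' @param env an `envelope_series`.
#' @return a `phase_series` of the same length and rate.
#' @export
instantaneous_phase <- function(env) {
  stopifnot(inherits(env, "envelope_series"))
  ph <- Arg(analytic_signal(env$values))
  ph[ph == -pi] <- pi
  phase_series(ph, env$rate, env$t0)
}

#' Detect burst onsets in an amplitude envelope
#'
#' Peak-picking onset detector for rhythmic unit trains: local maxima of the
#' smoothed envelope above `threshold` times its maximum, separated by at
#' least `min_separation`. Used to measure the realized unit presentation
#' rate of synthesized or recorded audio.
#'
#' @param env an `envelope_series` (unfiltered).
#' @param threshold fraction of the envelope maximum a peak must exceed.
#' @param min_separation minimum spacing between detected onsets, s.
#' @return vector of onset (peak) times in seconds.
#' @export
detect_onsets <- function(env, threshold = 0.3, min_separation = 0.1) {
  stopifnot(inherits(env, "envelope_series"))
  v <- env$values
  n <- length(v)
  if (n < 3) return(numeric(0))
  is_peak <- c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n],
               FALSE) & v > threshold * max(v)
  idx <- which(is_peak)
  if (length(idx) == 0) return(numeric(0))
  min_gap <- min_separation * env$rate
  keep <- idx[1]
  for (i in idx[-1]) {
    if (i - keep[length(keep)] >= min_gap) keep <- c(keep, i)
  }
  env$t0 + (keep - 1) / env$rate
}
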