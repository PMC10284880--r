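#' Phase-locking value of two phase segments
#'
#' `PLV = |sum(exp(i (theta1 - theta2)))| / T` over `T` time-aligned points:
#' the modulus of the mean resultant vector of the phase differences. 1 when
#' the phase difference is constant, near 0 when it is uniformly dispersed.
#'
#' @param theta1,theta2 numeric phase vectors (radians) or `phase_series`
#'   of equal length.
#' @return a value in `[0, 1]`.
#' @examples
#' plv(c(0, 1, 2), c(1, 2, 3)) # 1: constant difference
#' @export
plv <- function(theta1, theta2) {
  t1 <- if (inherits(theta1, "phase_series")) theta1$phases else theta1
  t2 <- if (inherits(theta2, "phase_series")) theta2$phases else theta2
  if (length(t1) == 0L || length(t1) != length(t2))
    stop_invalid("phase segments must be non-empty and of equal length")
  Mod(mean(exp(1i * (t1 - t2))))
}

#' Windowed phase-locking analysis
#'
#' Computes the PLV on sliding windows (default 5 s with 2 s overlap, i.e. a
#' 3 s step) anchored at the start of the series, discarding a trailing
#' partial window, and averages across windows. A 50-s recording yields 16
#' windows. Also reports the circular mean phase lag over the whole series.
#'
#' @param theta1 stimulus `phase_series` (or numeric phases, radians).
#' @param theta2 response `phase_series` of the same rate.
#' @param rate sampling rate in Hz, required when inputs are bare vectors.
#' @param window window length, s.
#' @param overlap window overlap, s (step = `window - overlap`).
#' @return an object of class `sync_result` with fields `window_plvs`,
#'   `mean_plv`, `mean_phase_lag` (degrees), `n_windows`, `window_starts`.
#' @export
windowed_plv <- function(theta1, theta2, rate = NULL, window = 5, overlap = 2) {
  t1 <- if (inherits(theta1, "phase_series")) theta1$phases else theta1
  t2 <- if (inherits(theta2, "phase_series")) theta2$phases else theta2
  if (is.null(rate)) {
    if (!inherits(theta1, "phase_series"))
      stop_invalid("rate must be given when phases are bare vectors")
    rate <- theta1$rate
    if (inherits(theta2, "phase_series") && theta2$rate != rate)
      stop_invalid("phase series have different sampling rates")
  }
  if (overlap >= window) stop_invalid("overlap must be smaller than window")
  len <- min(length(t1), length(t2))
  t1 <- t1[seq_len(len)]; t2 <- t2[seq_len(len)]
  n_win <- round(window * rate)
  step <- round((window - overlap) * rate)
  if (len < n_win)
    stop_invalid("series shorter than one analysis window")
  starts <- seq(1L, len - n_win + 1L, by = step)
  plvs <- vapply(starts, function(s) {
    idx <- s:(s + n_win - 1L)
    plv(t1[idx], t2[idx])
  }, numeric(1))
  structure(list(window_plvs = plvs,
                 mean_plv = mean(plvs),
                 mean_phase_lag = mean_phase_lag(t1, t2),
                 n_windows = length(plvs),
                 window_starts = (starts - 1L) / rate),
            class = "sync_result")
}

#' @export
print.sync_result <- function(x, ...) {
  cat(sprintf("Synchrony: mean PLV %.3f over %d windows; mean lag %+.1f deg\n",
              x$mean_plv, x$n_windows, x$mean_phase_lag))
  invisible(x)
}

#' @export
plot.sync_result <- function(x, ...) {
  plot(x$window_starts, x$window_plvs, type = "b", ylim = c(0, 1),
       xlab = "window start (s)", ylab = "PLV", ...)
  graphics::abline(h = x$mean_plv, lty = 2)
  invisible(x)
}

#' Circular mean phase lag between stimulus and response
#'
#' Circular mean of the pointwise phase differences (stimulus minus
#' response) over the whole series, reported in degrees in `(-180, 180]`.
#' Positive values mean the stimulus event precedes the response.
#'
#' @param theta1 stimulus phases (`phase_series` or radians).
#' @param theta2 response phases, same length.
#' @return lag in degrees.
#' @export
mean_phase_lag <- function(theta1, theta2) {
  t1 <- if (inherits(theta1, "phase_series")) theta1$phases else theta1
  t2 <- if (inherits(theta2, "phase_series")) theta2$phases else theta2
  if (length(t1) == 0L || length(t1) != length(t2))
    stop_invalid("phase segments must be non-empty and of equal length")
  rad2deg(Arg(mean(exp(1i * (t1 - t2)))))
}

#' Convert a phase lag to milliseconds
#'
#' `lag / 360 * cycle`: at the 4.3-4.7 units/s presentation rates one cycle
#' is about 222 ms, so a 54 degree lag corresponds to 33.3 ms.
#'
#' @param lag phase lag in degrees.
#' @param cycle cycle duration in ms.
#' @return lag in ms.
#' @examples
#' phase_lag_to_ms(54, 222.2) # 33.3
#' @export
phase_lag_to_ms <- function(lag, cycle = 1000 / 4.5) {
  check_scalar(cycle, "cycle")
  lag / 360 * cycle
}

# Full measurement chain: audio (or precomputed phase) -> envelope ->
# band-pass -> Hilbert phase. Returns a phase_series.
as_stim_phase <- function(x, env_rate = 200, band = c(3.3, 5.7),
                          method = "analytic") {
  if (inherits(x, "phase_series")) return(x)
  stopifnot(inherits(x, "audio_track"))
  instantaneous_phase(bandpass(compute_envelope(x, env_rate, method = method),
                               band[1], band[2]))
}

#' Measure stimulus-response synchrony
#'
#' The full measurement stack: amplitude envelopes of both recordings,
#' resampled to 200 Hz and band-passed 3.3-5.7 Hz, Hilbert phases, windowed
#' PLV (5-s windows, 2-s overlap) and the circular mean phase lag (stimulus
#' minus response). Both series are truncated to their common duration.
#'
#' @param response participant response [audio_track()] (or `phase_series`).
#' @param stimulus stimulus [audio_track()] (or a precomputed
#'   `phase_series`, convenient when scoring many responses against one
#'   stimulus).
#' @param window,overlap PLV window length and overlap, s.
#' @param band band-pass edges, Hz.
#' @param env_rate envelope sampling rate, Hz.
#' @param env_method envelope extractor, `"analytic"` or `"rectify"`.
#' @return a `sync_result` (see [windowed_plv()]).
#' @export
measure_sync <- function(response, stimulus, window = 5, overlap = 2,
                         band = c(3.3, 5.7), env_rate = 200,
                         env_method = "analytic") {
  th_s <- as_stim_phase(stimulus, env_rate, band, env_method)
  th_r <- as_stim_phase(response, env_rate, band, env_method)
  windowed_plv(th_s, th_r, window = window, overlap = overlap)
}

#' Sham synchrony against the training recording
#'
#' PLV between the sounds produced during the training step (rhythmic
#' production with no concurrent audio) and the first 10 s of the main-task
#' stimulus: a baseline for how synchronous an internally generated rhythm
#' is by chance. With 10-s segments the windowed analysis holds 2 full 5-s
#' windows (starting at 0 and 3 s) - not comparable in window count to the
#' 50-s task measurement.
#'
#' @param training training-step [audio_track()], nominally 10 s.
#' @param stimulus main-task stimulus [audio_track()] (>= `segment` s).
#' @param segment stimulus prefix length to compare against, s.
#' @param ... passed to [measure_sync()].
#' @return a `sync_result`.
#' @export
sham_synchrony <- function(training, stimulus, segment = 10, ...) {
  stopifnot(inherits(training, "audio_track"),
            inherits(stimulus, "audio_track"))
  common <- min(training$duration, segment, stimulus$duration)
  cut <- function(a, d) audio_track(a$samples[seq_len(round(d * a$sample_rate))],
                                    a$sample_rate)
  measure_sync(cut(training, common), cut(stimulus, common), ...)
}

#' Surrogate synchrony against fixed-rate audio
#'
#' Identical computation to the experimental synchrony but scored against a
#' fixed-rate (non-accelerating) version of the stimulus, e.g. from
#' [synth_surrogate()]. A responder tracking the accelerating tempo scores
#' lower here than against the true stimulus; a responder stuck at the base
#' rate scores higher.
#'
#' @param response main-task response [audio_track()] (or `phase_series`).
#' @param surrogate_stimulus fixed-rate [audio_track()] (or `phase_series`).
#' @param ... passed to [measure_sync()].
#' @return a `sync_result`.
#' @export
surrogate_synchrony <- function(response, surrogate_stimulus, ...) {
  measure_sync(response, surrogate_stimulus, ...)
}
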