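#' Accelerating rate schedule for rhythmic stimuli
#'
#' A rate schedule is an ordered set of plateaus, each holding the unit
#' presentation rate constant for a fixed duration. The default experimental
#' schedule steps from 4.3 to 4.7 units/s in 0.1 units/s increments, holding
#' each rate for 10 s, so the stimulus lasts 50 s.
#'
#' @param start_rate first plateau rate, units/s.
#' @param end_rate last plateau rate, units/s (`>= start_rate`).
#' @param step rate increment between plateaus, units/s (> 0).
#' @param plateau_duration duration of each plateau, s (> 0).
#' @return an object of class `rate_schedule`: a data frame with columns
#'   `rate` (units/s) and `duration` (s), one row per plateau, plus a
#'   `total_duration` attribute.
#' @examples
#' sched <- make_rate_schedule(4.3, 4.7, 0.1, 10)
#' sum(sched$duration) # 50
#' @export
make_rate_schedule <- function(start_rate = 4.3, end_rate = 4.7,
                               step = 0.1, plateau_duration = 10) {
  check_scalar(start_rate, "start_rate")
  check_scalar(end_rate, "end_rate")
  check_scalar(step, "step")
  check_scalar(plateau_duration, "plateau_duration")
  if (end_rate < start_rate)
    stop_invalid("end_rate must be >= start_rate")
  n <- floor((end_rate - start_rate) / step + 1e-9) + 1L
  rates <- start_rate + step * (seq_len(n) - 1L)
  out <- data.frame(rate = rates, duration = rep(plateau_duration, n))
  attr(out, "total_duration") <- n * plateau_duration
  class(out) <- c("rate_schedule", "data.frame")
  out
}

#' @export
print.rate_schedule <- function(x, ...) {
  cat(sprintf("Rate schedule: %d plateau(s), %.4g s total\n",
              nrow(x), schedule_duration(x)))
  cat(sprintf("  rates %s units/s, %.4g s each\n",
              paste(format(x$rate), collapse = ", "), x$duration[1]))
  invisible(x)
}

#' Total duration of a rate schedule
#' @param schedule a [make_rate_schedule()] object.
#' @return duration in seconds.
#' @export
schedule_duration <- function(schedule) {
  stopifnot(inherits(schedule, "rate_schedule"))
  sum(schedule$duration)
}

#' Acoustic-unit onset times implied by a rate schedule
#'
#' Within a plateau of rate `f`, consecutive onsets are `1/f` apart. The last
#' inter-onset interval before a plateau boundary is completed at the old
#' rate; the new rate applies from the following onset, so phase is carried
#' across boundaries rather than reset.
#'
#' @param schedule a [make_rate_schedule()] object.
#' @return strictly increasing vector of onset times in seconds, starting at 0.
#' @examples
#' length(unit_onset_times(make_rate_schedule(4.3, 4.7, 0.1, 10))) # 225
#' @export
unit_onset_times <- function(schedule) {
  stopifnot(inherits(schedule, "rate_schedule"))
  if (nrow(schedule) == 0L) return(numeric(0))
  ends <- cumsum(schedule$duration)
  starts <- c(0, ends[-length(ends)])
  onsets <- vector("list", nrow(schedule))
  t_next <- 0
  for (i in seq_len(nrow(schedule))) {
    f <- schedule$rate[i]
    if (t_next >= ends[i] - 1e-12) next
    # number of onsets t_next + k/f strictly before the plateau end
    n_i <- ceiling((ends[i] - t_next) * f - 1e-9)
    onsets[[i]] <- t_next + (seq_len(n_i) - 1L) / f
    t_next <- t_next + n_i / f
  }
  unlist(onsets)
}

#' Logarithmically spaced frequencies
#'
#' `f_k = f_min * (f_max/f_min)^(k/(n-1))`, `k = 0 ... n-1`; the ratio between
#' consecutive frequencies is constant. With `(0.5, 2, 16)` this reproduces
#' the 16 tone frequencies of the variable-tone stimulus (in kHz).
#'
#' @param f_min,f_max band edges (any unit; the result is in the same unit).
#' @param n number of frequencies (>= 2).
#' @return increasing numeric vector of length `n`.
#' @examples
#' round(log_spaced_freqs(0.5, 2, 16), 2)
#' @export
log_spaced_freqs <- function(f_min = 0.5, f_max = 2, n = 16) {
  check_scalar(f_min, "f_min")
  check_scalar(f_max, "f_max")
  if (f_max <= f_min) stop_invalid("f_max must be > f_min")
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stop_invalid("n must be >= 2")
  k <- seq_len(n) - 1L
  f_min * (f_max / f_min)^(k / (n - 1))
}
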