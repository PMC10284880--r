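#' Participant profile for cohort simulation
#'
#' Describes one (class of) simulated participant: per-effector coupling and
#' natural rates, the coupling penalty applied when the stimulus units vary
#' in identity, production noise, and response timing conventions. High
#' synchronizers couple strongly to any stimulus; low synchronizers keep
#' strong coupling only for repeated-unit stimuli (`variable_multiplier`
#' shrinks their coupling for variable-identity stimuli) and their vocal
#' natural rate sits below the stimulation range, so weakly coupled
#' conditions drift.
#'
#' @param group `"high"` or `"low"`.
#' @param coupling_vocal,coupling_hands coupling strength per effector,
#'   rad/s.
#' @param variable_multiplier coupling multiplier applied when the stimulus
#'   has variable unit identity (speech, various tones).
#' @param natural_vocal,natural_hands intrinsic rates per effector, Hz.
#' @param phase_noise Wiener phase-noise intensity, rad/sqrt(s).
#' @param onset_jitter_vocal,onset_jitter_hands event timing jitter SD, s.
#' @param anticipation_vocal,anticipation_hands constant amount by which the
#'   motor event precedes the oscillator's phase crossing, s (the negative
#'   mean asynchrony of sensorimotor synchronization; for the vocal tract it
#'   offsets the ~50 ms articulatory delay of the acoustic onset).
#' @return a `participant_profile` list.
#' @export
participant_profile <- function(group = c("high", "low"),
                                coupling_vocal = 15, coupling_hands = 22,
                                variable_multiplier = if (group == "low") 0.15 else 1,
                                natural_vocal = if (group == "low") 3.8 else 4.5,
                                natural_hands = 2.0,
                                phase_noise = 2,
                                onset_jitter_vocal = 0.022,
                                onset_jitter_hands = 0.012,
                                anticipation_vocal = 0.05,
                                anticipation_hands = 0) {
  group <- match.arg(group)
  structure(list(group = group,
                 coupling = c(vocal_tract = coupling_vocal,
                              hands = coupling_hands),
                 variable_multiplier = variable_multiplier,
                 natural = c(vocal_tract = natural_vocal,
                             hands = natural_hands),
                 phase_noise = phase_noise,
                 onset_jitter = c(vocal_tract = onset_jitter_vocal,
                                  hands = onset_jitter_hands),
                 anticipation = c(vocal_tract = anticipation_vocal,
                                  hands = anticipation_hands)),
            class = "participant_profile")
}

#' Default high/low profile templates
#' @return named list with `high` and `low` [participant_profile()]s.
#' @export
default_profiles <- function() {
  list(high = participant_profile("high"),
       low = participant_profile("low"))
}

#' Prepare stimuli and their phase series for cohort simulation
#'
#' Synthesizes the speech and tone stimuli on the default accelerating
#' schedule plus their fixed-rate 4.3 units/s surrogates, and precomputes
#' the envelope phase series that every simulated participant is scored
#' against (full task, and the first 10 s for sham synchrony).
#'
#' @param sample_rate audio sample rate, Hz.
#' @param seed RNG seed for unit orders.
#' @param schedule a [make_rate_schedule()]; default accelerating schedule.
#' @param surrogate_rate fixed surrogate rate, units/s.
#' @return a `prepared_stimuli` list with per-type audio and phases.
#' @export
prepare_stimuli <- function(sample_rate = 8000, seed = 1, schedule = NULL,
                            surrogate_rate = 4.3) {
  if (is.null(schedule)) schedule <- make_rate_schedule()
  seeds <- derive_seeds(seed, 4)
  duration <- schedule_duration(schedule)
  out <- list(sample_rate = sample_rate, duration = duration)
  types <- c(speech = "speech", tones = "tones")
  variable <- c(speech = TRUE, tones = FALSE)
  for (i in seq_along(types)) {
    ty <- types[i]
    audio <- synth_stimulus(ty, schedule, seed = seeds[i],
                            sample_rate = sample_rate)
    surr <- synth_surrogate(ty, rate = surrogate_rate, duration = duration,
                            seed = seeds[i + 2], sample_rate = sample_rate)
    first10 <- audio_track(audio$samples[seq_len(round(10 * sample_rate))],
                           sample_rate)
    out[[ty]] <- list(audio = audio,
                      phase = as_stim_phase(audio),
                      phase10 = as_stim_phase(first10),
                      surrogate_phase = as_stim_phase(surr),
                      variable = variable[[ty]])
  }
  class(out) <- "prepared_stimuli"
  out
}

# Condition grid in canonical order: (speech-vt, speech-hands, tones-vt,
# tones-hands).
condition_grid <- function() {
  data.frame(stimulus = c("speech", "speech", "tones", "tones"),
             effector = c("vocal_tract", "hands", "vocal_tract", "hands"),
             key = c("speech_vt", "speech_hands", "tones_vt", "tones_hands"),
             stringsAsFactors = FALSE)
}

#' Simulate one participant through the full pipeline
#'
#' Runs the coupled oscillator, renders the response audio, and applies the
#' complete measurement stack for each of the four effector-stimulus
#' conditions; also computes the sham synchrony (free-running 10-s training
#' production vs. the first 10 s of the stimulus) and the surrogate
#' synchrony (task response vs. fixed-rate audio).
#'
#' @param profile a [participant_profile()].
#' @param stimuli a [prepare_stimuli()] object.
#' @param seed RNG seed.
#' @param articulatory_delay vocal acoustic onset delay, s.
#' @param session_cv log-normal CV of the session-to-session motor-state
#'   factor scaling phase noise and timing jitter per condition (each
#'   condition is recorded in a separate session, hours apart).
#' @return a one-row data frame: `plv_*`, `lag_*`, `sham_*`, `surr_*` for
#'   the four condition keys, plus `true_group`.
#' @export
simulate_participant <- function(profile, stimuli, seed = 1,
                                 articulatory_delay = 0.05,
                                 session_cv = 0.3) {
  stopifnot(inherits(profile, "participant_profile"),
            inherits(stimuli, "prepared_stimuli"))
  grid <- condition_grid()
  seeds <- matrix(derive_seeds(seed, 7 * nrow(grid)), nrow = nrow(grid))
  rec <- list(true_group = profile$group)
  for (i in seq_len(nrow(grid))) {
    st <- stimuli[[grid$stimulus[i]]]
    eff <- grid$effector[i]
    K <- profile$coupling[[eff]] *
      if (st$variable) profile$variable_multiplier else 1
    session <- with_seed(seeds[i, 5],
                         exp(stats::rnorm(1, sd = session_cv)))
    par_task <- oscillator_params(natural_rate = profile$natural[[eff]],
                                  coupling = K,
                                  phase_noise = profile$phase_noise * session,
                                  onset_jitter = profile$onset_jitter[[eff]] *
                                    session,
                                  initial_phase = with_seed(seeds[i, 6],
                                    stats::runif(1, -pi, pi)))
    events <- simulate_oscillator(st$phase, par_task, seed = seeds[i, 1])
    events <- events - profile$anticipation[[eff]]
    events <- events[events >= 0]
    resp <- render_response_audio(events, eff, duration = stimuli$duration,
                                  sample_rate = stimuli$sample_rate,
                                  seed = seeds[i, 2],
                                  articulatory_delay = articulatory_delay)
    th_resp <- as_stim_phase(resp)
    res <- windowed_plv(st$phase, th_resp)
    surr <- windowed_plv(st$surrogate_phase, th_resp)
    # training: free-running production, no stimulus
    par_free <- oscillator_params(natural_rate = profile$natural[[eff]],
                                  coupling = 0,
                                  phase_noise = profile$phase_noise * session,
                                  onset_jitter = profile$onset_jitter[[eff]] *
                                    session,
                                  initial_phase = with_seed(seeds[i, 7],
                                    stats::runif(1, -pi, pi)))
    ev_tr <- simulate_oscillator(NULL, par_free, duration = 10,
                                 seed = seeds[i, 3])
    train <- render_response_audio(ev_tr - profile$anticipation[[eff]],
                                   eff, duration = 10,
                                   sample_rate = stimuli$sample_rate,
                                   seed = seeds[i, 4],
                                   articulatory_delay = articulatory_delay)
    sham <- windowed_plv(st$phase10, as_stim_phase(train))
    key <- grid$key[i]
    rec[[paste0("plv_", key)]] <- res$mean_plv
    rec[[paste0("lag_", key)]] <- res$mean_phase_lag
    rec[[paste0("sham_", key)]] <- sham$mean_plv
    rec[[paste0("surr_", key)]] <- surr$mean_plv
  }
  as.data.frame(rec, stringsAsFactors = FALSE)
}

# Jitter a template profile into an individual participant.
individualize_profile <- function(template, dispersion, seed) {
  with_seed(seed, {
    cv <- dispersion$coupling_cv
    ns <- dispersion$natural_sd
    participant_profile(
      group = template$group,
      coupling_vocal = template$coupling[["vocal_tract"]] *
        exp(stats::rnorm(1, sd = cv)),
      coupling_hands = template$coupling[["hands"]] *
        exp(stats::rnorm(1, sd = cv)),
      variable_multiplier = template$variable_multiplier *
        exp(stats::rnorm(1, sd = cv)),
      natural_vocal = template$natural[["vocal_tract"]] +
        stats::rnorm(1, sd = ns),
      natural_hands = template$natural[["hands"]] + stats::rnorm(1, sd = ns),
      phase_noise = template$phase_noise *
        exp(stats::rnorm(1, sd = dispersion$noise_cv %||% 0.5)),
      onset_jitter_vocal = template$onset_jitter[["vocal_tract"]] *
        exp(stats::rnorm(1, sd = dispersion$jitter_cv %||% 0.4)),
      onset_jitter_hands = template$onset_jitter[["hands"]] *
        exp(stats::rnorm(1, sd = dispersion$jitter_cv %||% 0.4)),
      anticipation_vocal = template$anticipation[["vocal_tract"]],
      anticipation_hands = template$anticipation[["hands"]])
  })
}

#' Simulate a full cohort
#'
#' Simulates `n_high` high and `n_low` low synchronizers (defaults 30 and
#' 21), each with couplings and natural rates jittered around the group
#' templates, through the full stimulus-response-measurement pipeline.
#' Years of musical training are drawn with a higher mean for the high
#' group; gender is assigned independently of group.
#'
#' @param n_high,n_low group sizes.
#' @param templates list with `high` and `low` [participant_profile()]s.
#' @param dispersion between-participant heterogeneity: `coupling_cv`
#'   (log-normal CV of couplings and multipliers), `natural_sd` (Gaussian SD
#'   of natural rates, Hz), `noise_cv` and `jitter_cv` (log-normal CVs of
#'   the phase-noise intensity and motor timing jitter). Defaults give within-group PLV spreads of roughly 0.1-0.15
#'   per condition, the between-subject variability typical of this task.
#' @param seed master RNG seed; every participant derives an independent
#'   child seed from it.
#' @param sample_rate audio sample rate for the simulated recordings, Hz.
#' @param stimuli optional [prepare_stimuli()] object to reuse across
#'   cohorts.
#' @return a `sync_cohort`: list with `records` (one row per participant:
#'   id, true_group, gender, musical_training, PLV/lag/sham/surrogate
#'   columns) and the generating settings.
#' @export
simulate_population <- function(n_high = 30, n_low = 21,
                                templates = default_profiles(),
                                dispersion = list(coupling_cv = 0.25,
                                                  natural_sd = 0.15,
                                                  noise_cv = 0.5,
                                                  jitter_cv = 0.4),
                                seed = 1, sample_rate = 8000,
                                stimuli = NULL) {
  if (n_high + n_low < 1) stop_invalid("empty cohort")
  if (is.null(stimuli))
    stimuli <- prepare_stimuli(sample_rate, seed = derive_seeds(seed, 1))
  n <- n_high + n_low
  groups <- rep(c("high", "low"), c(n_high, n_low))
  seeds <- matrix(derive_seeds(seed, 3 * n), nrow = n)
  covar_seeds <- derive_seeds(seed + 1, 2)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    prof <- individualize_profile(templates[[groups[i]]], dispersion,
                                  seeds[i, 1])
    rows[[i]] <- simulate_participant(prof, stimuli, seed = seeds[i, 2])
  }
  records <- do.call(rbind, rows)
  records <- cbind(id = sprintf("S%03d", seq_len(n)), records,
                   stringsAsFactors = FALSE)
  records$gender <- with_seed(covar_seeds[1],
    sample(c("F", "M"), n, replace = TRUE, prob = c(0.53, 0.47)))
  records$musical_training <- with_seed(covar_seeds[2], {
    mu <- ifelse(groups == "high", 6, 3)
    pmax(0, round(stats::rnorm(n, mean = mu, sd = 3)))
  })
  structure(list(records = records, n_high = n_high, n_low = n_low,
                 seed = seed, sample_rate = sample_rate),
            class = "sync_cohort")
}

#' @export
print.sync_cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d participants (%d high, %d low), seed %s\n",
              nrow(x$records), x$n_high, x$n_low, format(x$seed)))
  invisible(x)
}

#' @export
summary.sync_cohort <- function(object, ...) {
  rec <- object$records
  keys <- condition_grid()$key
  out <- aggregate(rec[paste0("plv_", keys)], by = list(group = rec$true_group),
                   FUN = mean)
  cat("Mean PLV by true group and condition:\n")
  print(out, digits = 3)
  invisible(out)
}

#' Extract the 4-D PLV matrix of a cohort
#'
#' @param cohort a `sync_cohort` (or its `records` data frame).
#' @return numeric matrix, one row per participant, columns in the order
#'   speech-vocal tract, speech-hands, tones-vocal tract, tones-hands.
#' @export
plv_matrix <- function(cohort) {
  rec <- if (inherits(cohort, "sync_cohort")) cohort$records else cohort
  as.matrix(rec[paste0("plv_", condition_grid()$key)])
}

#' Simulate the rhythmic-priming manipulation
#'
#' Runs the speech-vocal tract task (where low synchronizers are impaired)
#' under a priming condition. Active priming (prior synchronization to the
#' tone train with either effector) initializes the oscillator's vocal
#' natural rate at the priming stimulus's end rate (4.7 Hz), relaxing
#' exponentially back toward its baseline value during the task; passive
#' listening and baseline leave the natural rate untouched.
#'
#' @param profile a (low-group) [participant_profile()].
#' @param condition `"active_vocal"`, `"active_hands"`, `"passive"` or
#'   `"baseline"`.
#' @param stimuli a [prepare_stimuli()] object.
#' @param seed RNG seed.
#' @param primed_rate natural rate right after active priming, Hz.
#' @param relaxation time constant of the relaxation back to baseline, s
#'   (0 = instantaneous, i.e. no carryover).
#' @param articulatory_delay vocal acoustic onset delay, s.
#' @return list with `condition`, `plv` and `lag`.
#' @export
simulate_priming <- function(profile, condition = c("active_vocal",
                                                    "active_hands",
                                                    "passive", "baseline"),
                             stimuli, seed = 1, primed_rate = 4.7,
                             relaxation = 120, articulatory_delay = 0.05) {
  condition <- match.arg(condition)
  stopifnot(inherits(profile, "participant_profile"),
            inherits(stimuli, "prepared_stimuli"))
  st <- stimuli$speech
  base_rate <- profile$natural[["vocal_tract"]]
  n_grid <- length(st$phase$phases)
  t_grid <- (seq_len(n_grid) - 1) / st$phase$rate
  fn_t <- if (condition %in% c("active_vocal", "active_hands") &&
              relaxation > 0) {
    base_rate + (primed_rate - base_rate) * exp(-t_grid / relaxation)
  } else rep(base_rate, n_grid)
  seeds <- derive_seeds(seed, 3)
  K <- profile$coupling[["vocal_tract"]] *
    if (st$variable) profile$variable_multiplier else 1
  par <- oscillator_params(natural_rate = base_rate, coupling = K,
                           phase_noise = profile$phase_noise,
                           onset_jitter = profile$onset_jitter[["vocal_tract"]],
                           initial_phase = with_seed(seeds[1],
                                                     stats::runif(1, -pi, pi)))
  events <- simulate_oscillator(st$phase, par, seed = seeds[2],
                                natural_rate_t = fn_t)
  events <- events - profile$anticipation[["vocal_tract"]]
  events <- events[events >= 0]
  resp <- render_response_audio(events, "vocal_tract",
                                duration = stimuli$duration,
                                sample_rate = stimuli$sample_rate,
                                seed = seeds[3],
                                articulatory_delay = articulatory_delay)
  res <- windowed_plv(st$phase, as_stim_phase(resp))
  list(condition = condition, plv = res$mean_plv, lag = res$mean_phase_lag)
}
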