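test_that("envelope of a constant-amplitude tone is flat at that amplitude", {
  t <- (0:79999) / 8000
  a <- audio_track(0.6 * sin(2 * pi * 1000 * t), 8000)
  env <- compute_envelope(a)
  expect_equal(length(env$values), 10 * 200)
  mid <- env$values[200:1800]
  expect_true(all(abs(mid - 0.6) < 0.02))
  expect_true(all(env$values >= 0))
  expect_error(compute_envelope(audio_track(numeric(0), 8000)), "empty")
})

test_that("50-s track gives 10,000 envelope points at 200 Hz", {
  env <- fixture("tone_env", compute_envelope(fx_tone_train()))
  expect_equal(length(env$values), 10000L)
})

test_that("envelope of a 4.3 Hz modulated tone peaks at 4.3 Hz", {
  t <- (0:159999) / 8000
  mod <- abs(sin(2 * pi * 4.3 / 2 * t)) # |sin| half-waves at 4.3/s
  a <- audio_track(mod * sin(2 * pi * 1000 * t), 8000)
  env <- compute_envelope(a)
  # oracle: discrete Fourier transform peak over 0.5-10 Hz
  v <- env$values - mean(env$values)
  sp <- Mod(stats::fft(v))[1:200]
  freqs <- (0:199) * 200 / length(v)
  band <- freqs > 0.5 & freqs < 10
  expect_equal(freqs[band][which.max(sp[band])], 4.3, tolerance = 0.06)
})

test_that("band-pass preserves in-band tones and rejects out-of-band ones", {
  rate <- 200
  t <- (0:9999) / rate
  mk <- function(f) envelope_series_for_test(cos(2 * pi * f * t), rate)
  gain <- function(f) {
    out <- bandpass(mk(f))$values
    max(abs(out[2000:8000]))
  }
  expect_equal(gain(4.5), 1, tolerance = 0.05)
  expect_lt(20 * log10(gain(1.65)), -20) # one octave below the band
  expect_lt(20 * log10(gain(11.4)), -20) # one octave above
  expect_lt(20 * log10(gain(0.5)), -20)  # slow drift
  # zero in, zero out
  z <- bandpass(envelope_series_for_test(numeric(2000), rate))
  expect_true(all(abs(z$values) < 1e-12))
  expect_error(bandpass(mk(4.5), lo = 90, hi = 110), "band edges")
})

test_that("instantaneous phase advances at the signal frequency", {
  rate <- 200
  t <- (0:9999) / rate
  ph <- instantaneous_phase(envelope_series_for_test(cos(2 * pi * 4.5 * t),
                                                     rate))
  expect_true(all(ph$phases > -pi & ph$phases <= pi))
  up <- cumsum(c(ph$phases[1], audiomotor:::wrap_pi(diff(ph$phases))))
  slope <- stats::coef(stats::lm(up[500:9500] ~ t[500:9500]))[2]
  expect_equal(unname(slope), 2 * pi * 4.5, tolerance = 0.01)
  # quadrature identity: cos leads sin by pi/2
  ph_sin <- instantaneous_phase(
    envelope_series_for_test(sin(2 * pi * 4.5 * t), rate))
  d <- audiomotor:::wrap_pi(ph$phases - ph_sin$phases)[500:9500]
  expect_equal(mean(d), pi / 2, tolerance = 0.01)
  # sign flip shifts phase by pi everywhere
  ph_neg <- instantaneous_phase(
    envelope_series_for_test(-cos(2 * pi * 4.5 * t), rate))
  dd <- abs(audiomotor:::wrap_pi(ph$phases - ph_neg$phases))[500:9500]
  expect_equal(mean(dd), pi, tolerance = 1e-6)
})

test_that("PLV identities: constant difference, roots of unity, bounds", {
  th <- stats::runif(100, -pi, pi)
  expect_equal(plv(th, th), 1)
  expect_equal(plv(th, th - 0.7), 1)
  # T equally spaced differences sum to zero
  T_ <- 24
  expect_equal(plv(2 * pi * (0:(T_ - 1)) / T_, rep(0, T_)), 0,
               tolerance = 1e-12)
  expect_error(plv(numeric(0), numeric(0)), "non-empty")
  expect_error(plv(1:3, 1:4), "equal length")
})

test_that("PLV matches the brute-force complex-sum oracle to 1e-12", {
  set.seed(42)
  for (rep in 1:25) {
    T_ <- sample(2:50, 1)
    t1 <- stats::runif(T_, -pi, pi)
    t2 <- stats::runif(T_, -pi, pi)
    expect_equal(plv(t1, t2), brute_force_plv(t1 - t2), tolerance = 1e-12)
  }
})

test_that("PLV of independent uniform phases matches the sqrt(pi/4)/sqrt(T) law", {
  set.seed(7)
  T_ <- 1000
  r <- replicate(400, plv(stats::runif(T_, -pi, pi), stats::runif(T_, -pi, pi)))
  # E[R] = sqrt(pi / (4 T)) for uniform phase differences
  expect_equal(mean(r), sqrt(pi / (4 * T_)), tolerance = 0.1)
  expect_true(all(r >= 0 & r <= 1))
})

test_that("PLV is invariant under a global phase shift of either series", {
  set.seed(3)
  t1 <- stats::runif(500, -pi, pi)
  t2 <- stats::runif(500, -pi, pi)
  expect_equal(plv(t1, t2), plv(t1 + 1.1, t2), tolerance = 1e-12)
  expect_equal(plv(t1, t2), plv(t1, t2 - 2.2), tolerance = 1e-12)
})

test_that("50-s series with 5-s windows and 2-s overlap yields 16 windows", {
  th <- fx_tone_phase()
  res <- windowed_plv(th, th)
  expect_equal(res$n_windows, floor((50 - 5) / 3) + 1)
  expect_equal(res$window_starts, seq(0, 45, by = 3))
  expect_equal(res$mean_plv, 1, tolerance = 1e-9)
  expect_equal(res$mean_plv, mean(res$window_plvs))
  expect_error(windowed_plv(th$phases[1:100], th$phases[1:100], rate = 200),
               "shorter than one")
})

test_that("windowed PLV of independent noise phases sits at the chance level", {
  set.seed(11)
  n <- 10000
  res <- windowed_plv(stats::runif(n, -pi, pi), stats::runif(n, -pi, pi),
                      rate = 200)
  expect_lt(res$mean_plv, 0.06) # chance ~ sqrt(pi/4)/sqrt(1000) = 0.028
  expect_gt(res$mean_plv, 0.005)
})

test_that("mean phase lag recovers constant offsets and circular means", {
  th <- stats::runif(2000, -pi, pi)
  expect_equal(mean_phase_lag(th, th - pi / 6), 30, tolerance = 1e-9)
  expect_equal(mean_phase_lag(th, th), 0)
  # von Mises(54 deg, kappa = 4) differences: circular-mean consistency
  set.seed(5)
  d <- rvonmises(10000, 54 * pi / 180, 4)
  expect_equal(mean_phase_lag(d, rep(0, length(d))), 54, tolerance = 1)
})

test_that("mean phase lag agrees with a grid-search circular mean", {
  # oracle: angle minimizing the summed circular (1 - cos) distance, the
  # variational characterization of the circular mean
  set.seed(9)
  for (rep in 1:5) {
    d <- rvonmises(300, stats::runif(1, -pi, pi), 2)
    grid <- seq(-180, 180, by = 0.1)
    cost <- vapply(grid, function(g)
      sum(1 - cos((d * 180 / pi - g) * pi / 180)), numeric(1))
    expect_lt(audiomotor:::circ_dist_deg(mean_phase_lag(d, rep(0, 300)),
                                         grid[which.min(cost)]), 0.5)
  }
})

test_that("phase-lag-to-milliseconds conversion matches the printed value", {
  expect_equal(round(phase_lag_to_ms(54, 222.2), 1), 33.3)
  expect_equal(phase_lag_to_ms(360, 217), 217)
  expect_equal(phase_lag_to_ms(15.2, 222.2), 15.2 / 360 * 222.2)
  expect_equal(round(phase_lag_to_ms(15.2, 222.2), 2), 9.38)
})

test_that("measuring each stimulus against itself is near-perfect synchrony", {
  for (type in c("tones", "same_tone", "various_tones", "speech")) {
    st <- synth_stimulus(type, sample_rate = 8000, seed = 3)
    res <- measure_sync(st, st)
    expect_gte(res$mean_plv, 0.99)
    expect_lte(abs(res$mean_phase_lag), 2)
  }
})

test_that("delaying the response raises the lag by 360 * dt / cycle degrees", {
  stim <- fx_tone_train()
  th <- fx_tone_phase()
  base <- measure_sync(stim, th)$mean_phase_lag
  for (dms in c(10, 20, 30)) {
    d <- round(dms / 1000 * 8000)
    delayed <- audio_track(c(numeric(d),
                             stim$samples[1:(length(stim$samples) - d)]),
                           8000)
    shift <- measure_sync(delayed, th)$mean_phase_lag - base
    expect_lt(abs(shift - 360 * dms / 222.2), 5)
  }
})

test_that("sham synchrony is high for a copied segment, low for detuned rates", {
  stim <- fx_tone_train()
  first10 <- audio_track(stim$samples[1:(10 * 8000)], 8000)
  same <- sham_synchrony(first10, stim)
  expect_equal(same$n_windows, 2L) # 10-s segments: windows at 0 and 3 s
  expect_gte(same$mean_plv, 0.99)
  # free production at 3.5 Hz vs the 4.3 Hz opening: drifting phase
  tr <- synth_surrogate("tones", rate = 3.5, duration = 10, sample_rate = 8000)
  detuned <- sham_synchrony(tr, stim)
  expect_lt(detuned$mean_plv, 0.3)
  short <- audio_track(stim$samples[1:8000], 8000)
  expect_error(sham_synchrony(short, stim), "shorter than one")
})

test_that("surrogate synchrony separates accelerating from fixed responders", {
  stim <- fx_tone_train()
  surr <- fixture("surr_tones", synth_surrogate("tones", sample_rate = 8000))
  th_stim <- fx_tone_phase()
  th_surr <- audiomotor:::as_stim_phase(surr)
  # response = surrogate audio: perfect against the surrogate
  expect_equal(surrogate_synchrony(surr, th_surr)$mean_plv, 1,
               tolerance = 1e-9)
  # responder tracking the accelerating stimulus: surrogate < experimental
  expect_lt(surrogate_synchrony(stim, th_surr)$mean_plv,
            measure_sync(stim, th_stim)$mean_plv)
  # responder stuck at 4.3 Hz: surrogate > experimental
  expect_gt(surrogate_synchrony(surr, th_surr)$mean_plv,
            measure_sync(surr, th_stim)$mean_plv)
})
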