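# Shared fixtures, built once per test session.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# default tone train at 8 kHz (synthesis itself is fast; envelope reused)
fx_tone_train <- function() {
  fixture("tone_train", synth_stimulus("tones", sample_rate = 8000))
}

fx_tone_phase <- function() {
  fixture("tone_phase", audiomotor:::as_stim_phase(fx_tone_train()))
}

# prepared stimuli shared by all simulation tests
fx_prep <- function() {
  fixture("prep", prepare_stimuli(sample_rate = 8000, seed = 99))
}

# one default-size cohort shared by simulation/analysis tests
fx_cohort <- function() {
  fixture("cohort", simulate_population(seed = 101, stimuli = fx_prep()))
}

# von Mises sampler (Best & Fisher rejection algorithm); independent of the
# package, used as the oracle distribution in circular tests.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1
    }
  }
  atan2(sin(out), cos(out))
}

# Brute-force mean resultant modulus, the independent PLV oracle.
brute_force_plv <- function(d) {
  s <- 0 + 0i
  for (k in seq_along(d)) s <- s + complex(modulus = 1, argument = d[k])
  Mod(s) / length(d)
}

envelope_series_for_test <- function(values, rate) {
  audiomotor:::envelope_series(values, rate)
}
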