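# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code; no binary fixtures.

# A small, fast cohort configuration (2 + 2 animals, 4 flashes).
tiny_config <- function(..., seed = 42) {
  sim_config(n_wt = 2, n_model = 2,
             protocol = c(0.1, 1, 3, 25),
             seed = seed, ...)
}

# Hand-built recording on a uniform grid (fs in Hz, time in ms).
make_recording <- function(voltage, fs = 1000, t_start = -20,
                           adaptation = "DA", luminance = 3,
                           animal_id = "x1", group = "WT") {
  n <- length(voltage)
  time <- t_start + (seq_len(n) - 1) * 1000 / fs
  erg_recording(animal_id, group, flash_stimulus(luminance, adaptation),
                fs, time, voltage)
}

# Piecewise-smooth synthetic trace: pre-flash zeros, then arbitrary lobes
# supplied as gaussians (centre ms, sd ms, amplitude uV; negative = trough).
gauss_trace <- function(time, lobes) {
  v <- numeric(length(time))
  for (lb in lobes) {
    v <- v + lb$amp * exp(-(time - lb$at)^2 / (2 * lb$sd^2))
  }
  v
}

# Brute-force extremum oracle over a half-open window (lo, hi].
bf_min <- function(time, v, lo, hi) {
  idx <- which(time > lo & time <= hi)
  i <- idx[which.min(v[idx])]
  list(value = v[i], time = time[i])
}
bf_max <- function(time, v, lo, hi) {
  idx <- which(time > lo & time <= hi)
  i <- idx[which.max(v[idx])]
  list(value = v[i], time = time[i])
}

# Random valid measurement table for round-trip tests.
random_measurement_table <- function(n_animals = 3, lums = c(0.1, 1, 10)) {
  rows <- list()
  for (a in seq_len(n_animals)) {
    for (l in lums) {
      for (ad in c("DA", "LA")) {
        rows[[length(rows) + 1L]] <- component_row(
          sprintf("m%02d", a), if (a %% 2) "WT" else "MODEL", ad, l,
          a_amp = runif(1, 0, 300), a_it = runif(1, 5, 30),
          a_fixed_amp = runif(1, 0, 100),
          b_amp = runif(1, 0, 700), b_it = runif(1, 20, 80),
          mop_amp = runif(1, 0, 80), op_time_sum = runif(1, 60, 160),
          phnr_amp = if (ad == "LA") runif(1, 0, 40) else NA_real_,
          phnr_it = if (ad == "LA") runif(1, 60, 120) else NA_real_,
          flags = if (runif(1) < 0.3) c("a_absent", "ops_absent") else
            character())
      }
    }
  }
  measurement_table(rows)
}
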