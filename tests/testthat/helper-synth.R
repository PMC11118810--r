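# shared fixtures, built once per test run

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# small full session + its source projection (expensive; reused)
small_session <- function() {
  memo("small_session", simulate_session(sim_config(n_trials = 40, seed = 21)))
}

small_sources <- function() {
  memo("small_sources", {
    ses <- small_session()
    filt <- eloreta_filter(reduce_orientation(ses$leadfield))
    project_sources(filt, ses$eeg)
  })
}

# EMG time axis used across MEP tests
emg_time_ms <- function(fs = 1000) seq(-500, by = 1000 / fs, length.out = fs)

# circular absolute difference
circ_abs <- function(a, b) abs(atan2(sin(a - b), cos(a - b)))

# independent reference implementation of column-wise phase walks
# (used as an oracle against the generator's own path)
oracle_phase_walk <- function(times, n, f, sigma) {
  sapply(seq_len(n), function(i) {
    th <- cumsum(c(0, rnorm(length(times) - 1, sd = sigma * sqrt(diff(times)))))
    runif(1, -pi, pi) + 2 * pi * f * times + th
  })
}
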