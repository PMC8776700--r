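# Shared trace fixtures, built in code at test time.

# Stationary noiseless raised-cosine trace (periods commensurate with the
# sampling rate so that troughs land exactly on samples).
stationary_trace <- function(duration_s = 30, amplitude = c(4, 10, 2.5),
                             period_s = 3, rate = 30, seed = 1) {
  generate_trace(waveform_spec(
    duration_s = duration_s, sample_rate_hz = rate,
    base_amplitude_mm = amplitude, base_period_s = period_s, seed = seed))
}

# Constant-drift noiseless trace.
drifting_trace <- function(drift_cc = -0.3, duration_s = 60,
                           amplitude = c(4, 10, 2.5), period_s = 3,
                           seed = 1, ...) {
  generate_trace(waveform_spec(
    duration_s = duration_s, base_amplitude_mm = amplitude,
    base_period_s = period_s,
    drift_rate_mm_per_s = c(0, drift_cc, 0), seed = seed, ...))
}

# The seeded 148-trace default cohort, generated once per test run.
cohort_cache <- new.env(parent = emptyenv())
default_cohort <- function(seed = 1) {
  key <- paste0("s", seed)
  if (is.null(cohort_cache[[key]]))
    cohort_cache[[key]] <- generate_cohort(seed = seed)
  cohort_cache[[key]]
}
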