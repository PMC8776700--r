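test_that("noiseless deterministic spec yields an exact raised cosine", {
  sp <- waveform_spec(duration_s = 20, sample_rate_hz = 30,
                      base_amplitude_mm = c(10, 10, 10), base_period_s = 4,
                      seed = 7)
  tr <- generate_trace(sp)
  expected <- 10 * (1 - cos(2 * pi * tr$time_s / 4)) / 2
  for (d in c("ap", "cc", "lr")) {
    expect_equal(unname(tr$pos[, d]), expected, tolerance = 1e-12)
    expect_equal(min(tr$pos[, d]), 0)
    expect_equal(max(tr$pos[, d]), 10)
  }
})

test_that("expiration troughs sit on the drifting baseline", {
  tr <- drifting_trace(drift_cc = 0.3, duration_s = 100, period_s = 3)
  cyc <- attr(tr, "cycles")
  # period 3 s at 30 Hz: cycle starts are exact samples, value = baseline
  idx <- round(cyc$start_s * 30) + 1L
  idx <- idx[idx <= length(tr$time_s)]
  expect_equal(unname(tr$pos[idx, "cc"]), 0.3 * tr$time_s[idx],
               tolerance = 1e-9)
  # consecutive troughs differ by drift * period
  dtr <- diff(tr$pos[idx, "cc"])
  expect_equal(unname(dtr), rep(0.3 * 3, length(dtr)), tolerance = 1e-9)
})

test_that("zero-variability signal is exactly periodic", {
  tr <- stationary_trace(duration_s = 20, period_s = 2.5)
  lag <- round(2.5 * 30)
  n <- length(tr$time_s)
  expect_equal(tr$pos[seq_len(n - lag) + lag, ],
               tr$pos[seq_len(n - lag), ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("a fixed seed reproduces the trace bit-identically", {
  sp <- waveform_spec(duration_s = 40, base_amplitude_mm = c(4, 10, 2),
                      base_period_s = 3, amplitude_cv = 0.2, period_cv = 0.2,
                      noise_sd_mm = 0.5, drift_rate_mm_per_s = c(0, -0.2, 0),
                      seed = 123)
  expect_identical(generate_trace(sp)$pos, generate_trace(sp)$pos)
  sp2 <- waveform_spec(duration_s = 40, base_amplitude_mm = c(4, 10, 2),
                       base_period_s = 3, amplitude_cv = 0.2,
                       period_cv = 0.2, noise_sd_mm = 0.5,
                       drift_rate_mm_per_s = c(0, -0.2, 0), seed = 124)
  expect_false(identical(generate_trace(sp)$pos, generate_trace(sp2)$pos))
})

test_that("invalid spec fields raise errors naming the field", {
  expect_error(waveform_spec(duration_s = -1), "duration_s")
  expect_error(waveform_spec(duration_s = 10, sample_rate_hz = 0),
               "sample_rate_hz")
  expect_error(waveform_spec(duration_s = 10, base_period_s = Inf),
               "base_period_s")
  expect_error(waveform_spec(duration_s = 10, noise_sd_mm = -0.1),
               "noise_sd_mm")
  expect_error(waveform_spec(duration_s = 10,
                             base_amplitude_mm = c(-1, 10, 2)),
               "base_amplitude_mm")
  expect_error(waveform_spec(duration_s = 10,
                             drift_rate_mm_per_s = c(0, NA, 0)),
               "drift_rate_mm_per_s")
  expect_error(waveform_spec(duration_s = 10, seed = 1.5), "seed")
})

test_that("piecewise drift integrates to a piecewise-linear baseline", {
  seg <- cbind(t_s = c(0, 10, 20), rate = c(0.5, -0.5, 0))
  sp <- waveform_spec(duration_s = 30, base_amplitude_mm = c(0, 0, 0),
                      base_period_s = 3,
                      drift_rate_mm_per_s = list(seg, seg, seg), seed = 1)
  tr <- generate_trace(sp)
  b <- function(t) ifelse(t < 10, 0.5 * t,
                          ifelse(t < 20, 5 - 0.5 * (t - 10), 0))
  expect_equal(unname(tr$pos[, "cc"]), b(tr$time_s), tolerance = 1e-12)
})

test_that("trough-to-trough regression recovers the drift rate within 1%", {
  tr <- drifting_trace(drift_cc = 0.42, duration_s = 90, period_s = 3.1)
  ep <- detect_expiration_points(tr, "cc")
  fit <- stats::lm(ep$a_ep ~ ep$t_ep)
  expect_lt(abs(unname(stats::coef(fit)[2]) / 0.42 - 1), 0.01)
})

test_that("cohort generation is seeded, sized and parameter-faithful", {
  expect_error(generate_cohort(n_traces = 0), "n_traces")
  one <- generate_cohort(n_traces = 1, seed = 9)
  expect_length(one, 1L)
  # the cohort trace is reproduced exactly by its own stored spec
  expect_identical(one[[1]]$pos, generate_trace(attr(one[[1]], "spec"))$pos)

  pop <- sbrt_cohort_population()[c(1, 6), ]
  pop$n_traces <- c(3, 2)
  small <- generate_cohort(population = pop, seed = 4)
  expect_length(small, 5L)
  expect_identical(
    lapply(generate_cohort(population = pop, seed = 4), `[[`, "pos"),
    lapply(small, `[[`, "pos"))
  ids <- vapply(small, function(tr) tr$meta$id, character(1))
  expect_length(unique(ids), 5L)
})

test_that("pooled cohort draws match the target population statistics", {
  # amplitude 10.1 +/- 2.2 mm, period 3.0 +/- 0.6 s across traces
  cohort <- generate_cohort(n_traces = 120, seed = 31)
  amp <- vapply(cohort, function(tr) attr(tr, "spec")$base_amplitude_mm[2],
                numeric(1))
  per <- vapply(cohort, function(tr) attr(tr, "spec")$base_period_s,
                numeric(1))
  expect_lt(abs(mean(amp) - 10.1), 2 * stats::sd(amp) / sqrt(length(amp)))
  expect_lt(abs(mean(per) - 3.0), 2 * stats::sd(per) / sqrt(length(per)))
})
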