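test_that("phase is anchored at inspiration peaks and troughs land at 0.5", {
  tr <- stationary_trace(duration_s = 30, period_s = 3)
  pa <- assign_phase(tr)
  expect_equal(unname(pa$phase_fraction[pa$anchors[-length(pa$anchors)]]),
               rep(0, length(pa$anchors) - 1L))
  # troughs: deepest in-cycle samples sit at phase 0.5 (+/- one sample)
  troughs <- detect_expiration_points(tr, "cc")$idx
  troughs <- troughs[troughs >= pa$anchors[1] &
                       troughs < pa$anchors[length(pa$anchors)]]
  expect_true(all(abs(pa$phase_fraction[troughs] - 0.5) <= 1 / 90 + 1e-9))
  # out-of-cycle samples are flagged
  expect_true(all(is.na(pa$phase_fraction[seq_len(pa$anchors[1] - 1L)])))
  expect_false(any(pa$in_cycle[pa$anchors[length(pa$anchors)]:
                                 length(tr$time_s)]))
})

test_that("irregular cycles still map peak-to-peak onto [0,1)", {
  sp <- waveform_spec(duration_s = 45, base_amplitude_mm = c(4, 10, 2.5),
                      base_period_s = 3, period_cv = 0.25,
                      amplitude_cv = 0.2, seed = 21)
  pa <- assign_phase(generate_trace(sp))
  f <- pa$phase_fraction[pa$in_cycle]
  expect_true(all(f >= 0 & f < 1))
  expect_true(all(diff(pa$cycle_index[pa$in_cycle]) >= 0))
})

test_that("amplitude calibration uses exactly the first cycles", {
  # amplitude 10 for the first four cycles, 20 afterwards
  t <- seq(0, 30, by = 1 / 30)
  a <- ifelse(t < 12, 10, 20)
  x <- a * (1 - cos(2 * pi * t / 3)) / 2
  tr <- resp_trace(t, 0.4 * x, x, 0.25 * x)
  cal <- calibrate_amplitude(tr, "cc", n_calibration_cycles = 3)
  expect_equal(unname(cal), c(0, 10))
  expect_error(calibrate_amplitude(stationary_trace(duration_s = 7,
                                                    period_s = 3),
                                   n_calibration_cycles = 5),
               "cycles")
})

test_that("stationary non-drifting calibration spans (0, amplitude)", {
  cal <- calibrate_amplitude(stationary_trace(duration_s = 30), "cc")
  expect_equal(unname(cal), c(0, 10), tolerance = 1e-9)
})

test_that("drifted troughs push the amplitude fraction below zero unclipped", {
  tr <- drifting_trace(drift_cc = -0.3, duration_s = 60)
  pa <- assign_phase(tr)
  expect_lt(min(pa$amplitude_fraction, na.rm = TRUE), -0.5)
})

test_that("phase window [0,1] turns every in-cycle sample on", {
  tr <- stationary_trace()
  pa <- assign_phase(tr)
  m <- compute_gating_mask(pa, gating_window("phase", "expiration",
                                             intervals = list(c(0, 1))))
  expect_identical(m$on, pa$in_cycle)
  expect_equal(m$duty_cycle, mean(pa$in_cycle))
  expect_equal(m$duty_cycle_in_cycle, 1)
})

test_that("phase-method duty cycle matches the window width", {
  tr <- stationary_trace(duration_s = 60, period_s = 3)
  pa <- assign_phase(tr)
  samples_per_cycle <- 90
  for (ph in c("expiration", "transition", "inspiration")) {
    w <- gating_window("phase", ph)
    width <- sum(vapply(w$intervals, diff, numeric(1)))
    m <- compute_gating_mask(pa, w)
    expect_lt(abs(m$duty_cycle_in_cycle - width),
              2 / samples_per_cycle + 1e-9)
  }
})

test_that("interior amplitude windows bound beam-on positions exactly", {
  tr <- drifting_trace(drift_cc = -0.2, duration_s = 60)
  pa <- assign_phase(tr)
  w <- gating_window("amplitude", "transition")   # [0.35, 0.65], interior
  m <- compute_gating_mask(pa, w)
  cal <- pa$calibration
  y <- tr$pos[m$on, "cc"]
  lo <- cal$a_min + 0.35 * (cal$a_max - cal$a_min)
  hi <- cal$a_min + 0.65 * (cal$a_max - cal$a_min)
  expect_true(all(y >= lo & y <= hi))
})

test_that("open-ended amplitude windows follow the drifted signal", {
  tr <- drifting_trace(drift_cc = -0.3, duration_s = 90)
  pa <- assign_phase(tr)
  m_open <- compute_gating_mask(pa, gating_window("amplitude", "expiration"))
  m_strict <- compute_gating_mask(pa, gating_window("amplitude", "expiration"),
                                  strict_bounds = TRUE)
  # troughs that drifted below the calibration minimum stay beam-on
  below <- pa$amplitude_fraction < 0 & pa$in_cycle
  expect_true(any(m_open$on & below))
  expect_false(any(m_strict$on & below))
})

test_that("residual motion respects mask degeneracies and bounds", {
  tr <- stationary_trace(duration_s = 30)
  pa <- assign_phase(tr)
  all_on <- compute_gating_mask(pa, gating_window("phase", "expiration",
                                                  intervals = list(c(0, 1))))
  res <- compute_residual_motion(tr, all_on, pa)
  # all-on mask sees the full peak-to-peak amplitude each cycle
  expect_equal(unname(res$mean_mm), c(4, 10, 2.5), tolerance = 1e-6)
  # Euclidean 3D combination
  expect_equal(res$residual_3d_mm, sqrt(sum(res$mean_mm^2)))
  expect_true(res$residual_3d_mm <= sum(res$mean_mm) + 1e-12)
  expect_true(res$residual_3d_mm >= max(res$mean_mm) - 1e-12)

  off <- all_on
  off$on[] <- FALSE
  expect_warning(res0 <- compute_residual_motion(tr, off, pa), "off")
  expect_true(res0$all_off)
  expect_equal(unname(res0$mean_mm), c(0, 0, 0))

  # amplitude expiration window bounds the in-window range directly
  m_amp <- compute_gating_mask(pa, gating_window("amplitude", "expiration"))
  res_amp <- compute_residual_motion(tr, m_amp, pa)
  expect_lt(res_amp$mean_mm["cc"], 0.30 * 10 + 10 * pi / 3 / 30)
})

test_that("widening a gating window never decreases residual motion", {
  tr <- drifting_trace(drift_cc = -0.15, duration_s = 45, seed = 3)
  pa <- assign_phase(tr)
  widths <- list(c(0.45, 0.55), c(0.40, 0.60), c(0.35, 0.65), c(0.25, 0.75))
  res <- vapply(widths, function(iv) {
    m <- compute_gating_mask(pa, gating_window("phase", "expiration",
                                               intervals = list(iv)))
    compute_residual_motion(tr, m, pa)$mean_mm["cc"]
  }, numeric(1))
  expect_true(all(diff(res) >= -1e-12))
})

test_that("per-cycle residuals never exceed the cycle's full range", {
  sp <- waveform_spec(duration_s = 50, base_amplitude_mm = c(4, 10, 2.5),
                      base_period_s = 3, amplitude_cv = 0.2, period_cv = 0.2,
                      noise_sd_mm = 0.3, drift_rate_mm_per_s = c(0, -0.3, 0),
                      seed = 14)
  tr <- generate_trace(sp)
  pa <- assign_phase(tr)
  full <- compute_gating_mask(pa, gating_window("phase", "expiration",
                                                intervals = list(c(0, 1))))
  res_full <- compute_residual_motion(tr, full, pa)
  for (method in c("phase", "amplitude")) for (ph in c("expiration",
                                                       "transition",
                                                       "inspiration")) {
    m <- compute_gating_mask(pa, gating_window(method, ph))
    res <- compute_residual_motion(tr, m, pa)
    expect_true(all(res$per_cycle_mm <= res_full$per_cycle_mm + 1e-9))
    expect_true(all(res$per_cycle_mm >= 0))
  }
})

test_that("amplitude gating bounds the drifted in-window spread", {
  # interior window: beam-on spread is capped by the mapped window height,
  # while phase gating additionally accumulates the net baseline drift
  tr <- drifting_trace(drift_cc = -0.3, duration_s = 60)
  pa <- assign_phase(tr)
  cal <- pa$calibration
  m_amp <- compute_gating_mask(pa, gating_window("amplitude", "transition"))
  m_pha <- compute_gating_mask(pa, gating_window("phase", "transition"))
  spread <- function(m) diff(range(tr$pos[m$on, "cc"]))
  expect_lte(spread(m_amp), 0.30 * (cal$a_max - cal$a_min) + 1e-9)
  net_drift <- 0.3 * 60 * 0.8   # most of the beam elapses between windows
  expect_gt(spread(m_pha), spread(m_amp) + net_drift * 0.5)
})

test_that("amplitude gating reduces residual motion on drifted cohorts", {
  # lower-lobe-like drift (>= 0.3 mm/s): amplitude gating gives less mean 3D
  # residual motion than phase gating in the transition and inspiration
  # phases at the cohort level
  pop <- sbrt_cohort_population()[c(6, 9), ]
  pop$n_traces <- c(6, 6)
  cohort <- generate_cohort(population = pop, seed = 17)
  diffs <- do.call(rbind, lapply(cohort, function(tr)
    compare_gating_methods(tr)$differences))
  agg <- stats::aggregate(diffs["residual_3d_mm"], by = diffs["phase"],
                          FUN = mean)
  d3 <- stats::setNames(agg$residual_3d_mm, agg$phase)
  expect_gt(d3[["transition"]], 0)
  expect_gt(d3[["inspiration"]], 0)
})
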