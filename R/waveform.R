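#' Specification of a synthetic respiratory waveform
#'
#' Defines the quasi-periodic breathing model used by [generate_trace()]:
#' per direction `d`,
#' \deqn{x_d(t) = b_d(t) + s_d A_{k,d} \left(\frac{1-\cos 2\pi\phi(t)}{2}\right)^p + \epsilon(t)}
#' where `phi` advances by 1 per respiratory cycle, cycle `k` draws a
#' peak-to-peak amplitude `A[k,d] ~ Normal(base, cv*base)` truncated at 0 and
#' a period `T[k] ~ Normal(base, cv*base)` truncated at `0.2*base`, the
#' baseline `b_d(t)` integrates the (possibly piecewise-constant) drift rate,
#' and `epsilon ~ Normal(0, noise_sd)` is per-sample measurement noise.
#' With the default sign `s_d = +1`, inspiration is the positive extreme and
#' the expiration trough sits exactly on the drifting baseline.
#'
#' @param duration_s trace length, seconds (> 0).
#' @param sample_rate_hz sampling rate, Hz (> 0). Default 30, typical of
#'   fluoroscopic marker-tracking logs.
#' @param base_amplitude_mm per-direction peak-to-peak amplitude, mm
#'   (length 1 or 3, order AP/CC/LR, each >= 0).
#' @param base_period_s mean respiratory period, seconds (> 0).
#' @param drift_rate_mm_per_s baseline drift rate, mm/s. Either a numeric of
#'   length 1 or 3 (constant rate per direction), or a list of 3 elements
#'   (AP, CC, LR) where each element is a scalar or a two-column matrix /
#'   data.frame `(t_s, rate_mm_per_s)` giving a piecewise-constant rate from
#'   each breakpoint onwards (piecewise-linear baseline).
#' @param amplitude_cv,period_cv per-cycle coefficient of variation of the
#'   amplitude and period draws (>= 0).
#' @param noise_sd_mm per-sample Gaussian noise, mm (>= 0).
#' @param shape waveform sharpness exponent `p` (> 0). `1` (default) is a
#'   raised cosine; larger values sharpen the inspiration peak and let the
#'   signal dwell near expiration, as real breathing does.
#' @param sign per-direction orientation flag, `+1` or `-1` (length 1 or 3).
#'   `-1` inverts the axis so that inspiration is the negative extreme.
#' @param seed integer seed; a fixed seed yields a bit-identical trace.
#'
#' @return An object of class `waveform_spec`.
#' @export
waveform_spec <- function(duration_s,
                          sample_rate_hz = 30,
                          base_amplitude_mm = c(4, 10, 2.5),
                          base_period_s = 3,
                          drift_rate_mm_per_s = c(0, 0, 0),
                          amplitude_cv = 0,
                          period_cv = 0,
                          noise_sd_mm = 0,
                          shape = 1,
                          sign = c(1, 1, 1),
                          seed = 1L) {
  chk_scalar <- function(x, name, lower = 0, strict = TRUE) {
    if (length(x) != 1L || !is.finite(x) ||
        (strict && x <= lower) || (!strict && x < lower))
      stop("waveform_spec: field '", name, "' must be a finite scalar ",
           if (strict) "> " else ">= ", lower)
    as.numeric(x)
  }
  vec3 <- function(x, name) {
    if (length(x) == 1L) x <- rep(x, 3L)
    if (length(x) != 3L || !all(is.finite(x)))
      stop("waveform_spec: field '", name,
           "' must be finite of length 1 or 3")
    as.numeric(x)
  }
  duration_s <- chk_scalar(duration_s, "duration_s")
  sample_rate_hz <- chk_scalar(sample_rate_hz, "sample_rate_hz")
  base_period_s <- chk_scalar(base_period_s, "base_period_s")
  amplitude_cv <- chk_scalar(amplitude_cv, "amplitude_cv", strict = FALSE)
  period_cv <- chk_scalar(period_cv, "period_cv", strict = FALSE)
  noise_sd_mm <- chk_scalar(noise_sd_mm, "noise_sd_mm", strict = FALSE)
  shape <- chk_scalar(shape, "shape")
  base_amplitude_mm <- vec3(base_amplitude_mm, "base_amplitude_mm")
  if (any(base_amplitude_mm < 0))
    stop("waveform_spec: field 'base_amplitude_mm' must be >= 0 componentwise")
  sign <- vec3(sign, "sign")
  if (!all(sign %in% c(-1, 1)))
    stop("waveform_spec: field 'sign' must be +1 or -1 per direction")
  drift_rate_mm_per_s <- normalize_drift(drift_rate_mm_per_s)
  if (length(seed) != 1L || !is.finite(seed) || seed != round(seed))
    stop("waveform_spec: field 'seed' must be a single integer")
  structure(list(duration_s = duration_s, sample_rate_hz = sample_rate_hz,
                 base_amplitude_mm = base_amplitude_mm,
                 base_period_s = base_period_s,
                 drift_rate_mm_per_s = drift_rate_mm_per_s,
                 amplitude_cv = amplitude_cv, period_cv = period_cv,
                 noise_sd_mm = noise_sd_mm, shape = shape, sign = sign,
                 seed = as.integer(seed)),
            class = "waveform_spec")
}

# Canonical drift representation: list of 3 (ap, cc, lr), each a 2-column
# matrix (t_s, rate) with t_s[1] == 0, piecewise-constant rate.
normalize_drift <- function(drift) {
  as_segments <- function(x, name) {
    if (is.null(dim(x)) && length(x) == 1L) {
      if (!is.finite(x)) stop("waveform_spec: field 'drift_rate_mm_per_s' ",
                              "must be finite")
      return(cbind(t_s = 0, rate = as.numeric(x)))
    }
    m <- as.matrix(x)
    if (ncol(m) != 2L || !all(is.finite(m)))
      stop("waveform_spec: field 'drift_rate_mm_per_s' segments must be a ",
           "finite two-column (t_s, rate) table")
    if (is.unsorted(m[, 1], strictly = TRUE))
      stop("waveform_spec: field 'drift_rate_mm_per_s' segment times must be ",
           "strictly increasing")
    if (m[1, 1] != 0)
      m <- rbind(c(0, m[1, 2]), m)
    colnames(m) <- c("t_s", "rate")
    m
  }
  if (is.list(drift) && !is.data.frame(drift)) {
    if (length(drift) != 3L)
      stop("waveform_spec: field 'drift_rate_mm_per_s' list must have 3 ",
           "elements (AP, CC, LR)")
    return(lapply(drift, as_segments))
  }
  if (is.numeric(drift) && is.null(dim(drift))) {
    if (length(drift) == 1L) drift <- rep(drift, 3L)
    if (length(drift) != 3L || !all(is.finite(drift)))
      stop("waveform_spec: field 'drift_rate_mm_per_s' must be finite of ",
           "length 1 or 3")
    return(lapply(drift, function(r) cbind(t_s = 0, rate = r)))
  }
  stop("waveform_spec: field 'drift_rate_mm_per_s' must be numeric or a ",
       "list of per-direction segment tables")
}

# Integrate a piecewise-constant drift rate to a piecewise-linear baseline.
drift_baseline <- function(t, segments) {
  brk <- segments[, "t_s"]
  rate <- segments[, "rate"]
  base_at_brk <- c(0, cumsum(rate[-length(rate)] * diff(brk)))
  k <- findInterval(t, brk)
  k[k < 1L] <- 1L
  base_at_brk[k] + rate[k] * (t - brk[k])
}

draw_truncated_normal <- function(n, mean, sd, lower) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n); lower <- rep_len(lower, n)
  x <- stats::rnorm(n, mean, sd)
  for (i in seq_len(100)) {
    bad <- which(x <= lower)
    if (!length(bad)) break
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
  }
  bad <- x <= lower
  x[bad] <- lower[bad] + sd[bad] * 1e-3 + 1e-9
  x
}

#' Generate a synthetic respiratory trace
#'
#' Evaluates the waveform model of [waveform_spec()] on a uniform time grid.
#' The construction is deterministic given `spec$seed`.
#'
#' @param spec a [waveform_spec()].
#' @param meta optional identifier list stored in the trace.
#' @return A [resp_trace()] with attributes `spec` (the generating spec) and
#'   `cycles` (data frame of true cycle start times, periods and per-cycle
#'   amplitudes -- ground truth for parameter-recovery checks).
#' @export
generate_trace <- function(spec, meta = list()) {
  stopifnot(inherits(spec, "waveform_spec"))
  n <- floor(spec$duration_s * spec$sample_rate_hz) + 1L
  t <- (seq_len(n) - 1L) / spec$sample_rate_hz

  with_seed(spec$seed, {
    # periods first, then per-cycle amplitudes, then noise: fixed draw order
    n_guess <- ceiling(spec$duration_s / (0.2 * spec$base_period_s)) + 2L
    periods <- draw_truncated_normal(n_guess, spec$base_period_s,
                                     spec$period_cv * spec$base_period_s,
                                     0.2 * spec$base_period_s)
    k_used <- which(cumsum(periods) >= spec$duration_s)[1]
    if (is.na(k_used)) k_used <- n_guess
    periods <- periods[seq_len(k_used)]
    amps <- sapply(seq_len(3L), function(d) {
      base <- spec$base_amplitude_mm[d]
      if (base == 0) rep(0, k_used)
      else draw_truncated_normal(k_used, base, spec$amplitude_cv * base, 0)
    })
    amps <- matrix(amps, nrow = k_used)
    noise <- if (spec$noise_sd_mm > 0)
      matrix(stats::rnorm(3L * n, 0, spec$noise_sd_mm), ncol = 3L)
    else matrix(0, n, 3L)

    starts <- c(0, cumsum(periods))[seq_len(k_used)]
    k <- findInterval(t, starts)
    phi <- (t - starts[k]) / periods[k]
    shape_term <- ((1 - cos(2 * pi * phi)) / 2)^spec$shape
    pos <- sapply(seq_len(3L), function(d) {
      drift_baseline(t, spec$drift_rate_mm_per_s[[d]]) +
        spec$sign[d] * amps[k, d] * shape_term + noise[, d]
    })
    trace <- resp_trace(t, pos[, 1], pos[, 2], pos[, 3], meta = meta)
    attr(trace, "spec") <- spec
    attr(trace, "cycles") <- data.frame(
      start_s = starts, period_s = periods,
      amp_ap = amps[, 1], amp_cc = amps[, 2], amp_lr = amps[, 3])
    trace
  })
}

#' Representative lung SBRT cohort population
#'
#' Per-patient trace statistics for a 10-patient lung SBRT cohort treated
#' with fiducial-marker tracking: per-beam amplitude (dominant direction),
#' respiratory period and beam-on time, with tumour lobe location and the
#' number of intra-beam motion records per patient (148 in total). Used as
#' the default population for [generate_cohort()].
#'
#' @return data frame with one row per patient.
#' @export
sbrt_cohort_population <- function() {
  data.frame(
    patient = 1:10,
    location = c("mid", "mid", "mid", "upper", "upper",
                 "lower", "lower", "lower", "lower", "lower"),
    amplitude_mean_mm = c(14.0, 8.7, 8.3, 6.4, 9.3, 10.6, 13.4, 11.0, 10.5, 8.9),
    amplitude_sd_mm   = c(2.5, 1.6, 0.9, 1.2, 1.4, 2.5, 1.8, 3.4, 4.3, 2.2),
    period_mean_s     = c(2.7, 2.3, 2.1, 4.7, 2.2, 2.8, 3.0, 3.4, 3.3, 3.4),
    period_sd_s       = c(0.4, 0.2, 0.2, 0.7, 0.3, 0.5, 0.4, 0.9, 1.0, 1.1),
    beam_time_mean_s  = c(166, 179, 166, 166, 185, 122, 130, 145, 160, 138),
    beam_time_sd_s    = c(16, 22, 16, 20, 20, 14, 25, 10, 17, 12),
    n_traces          = c(10, 15, 13, 14, 20, 13, 14, 16, 18, 15),
    stringsAsFactors = FALSE)
}

# CC baseline-drift magnitude band (mm/s) by tumour lobe location; AP and LR
# scale at 0.55 and 0.50 of CC, matching the relative per-direction spread of
# intrafraction drift reported for marker-tracked lung targets.
drift_band <- function(location) {
  switch(location,
         upper = c(0.03, 0.13),
         mid   = c(0.10, 0.30),
         lower = c(0.30, 0.74),
         stop("unknown location '", location, "'"))
}

#' Generate a cohort of synthetic respiratory traces
#'
#' Draws per-trace waveform parameters from a population description and
#' generates independent traces. Reproducible: the same `seed` yields an
#' identical cohort.
#'
#' Two population forms are accepted. A data frame like
#' [sbrt_cohort_population()] (one row per patient with per-patient
#' amplitude/period/beam-time statistics, lobe location and trace count)
#' generates `n_traces` per patient row; lobe location sets the baseline
#' drift-rate band (CC magnitude: upper 0.03-0.13, mid 0.10-0.30, lower
#' 0.30-0.74 mm/s). Alternatively a named list of pooled parameters
#' (`amplitude_mean_mm`, `amplitude_sd_mm`, `period_mean_s`, `period_sd_s`,
#' `duration_mean_s`, `duration_sd_s`, `drift_cc_range`) with `n_traces`
#' draws a homogeneous cohort.
#'
#' The per-trace dominant (CC) amplitude is drawn from the patient
#' distribution; AP and LR amplitudes default to 0.40 and 0.25 of CC,
#' reflecting the usual dominance of cranial-caudal lung-tumour motion.
#' Baseline drift is piecewise-linear by default: segments of
#' `segment_range_s` duration run at the per-trace drift-rate magnitude with
#' a per-segment direction drawn with probability `p_drift_down` toward the
#' expiration side, and the cumulative baseline excursion is reflected at
#' `baseline_range_mm`. Per-cycle drift therefore matches the nominal rate
#' while the net intra-beam excursion stays anatomically plausible (a
#' sustained 0.7 mm/s over a 150 s beam would otherwise imply >100 mm of
#' travel). The direction bias (default 0.8) and the asymmetric excursion
#' bounds (default -8 to +3 mm) reflect the predominantly caudal --
#' expiration-ward -- baseline drift of a few millimetres reported for
#' marker-tracked lung targets as the patient relaxes.
#'
#' @param n_traces number of traces for a pooled-population draw; ignored
#'   when `population` is a per-patient data frame.
#' @param population population description (see Details); default
#'   [sbrt_cohort_population()].
#' @param seed integer master seed.
#' @param noise_sd_mm per-sample tracking noise, mm.
#' @param drift_model `"piecewise"` (alternating-sign segments, default) or
#'   `"constant"` (single sustained rate with random sign).
#' @param segment_range_s min/max drift-segment duration, seconds.
#' @param p_drift_down probability that a drift segment runs toward the
#'   expiration side (negative under the default sign convention).
#' @param baseline_range_mm reflecting bounds `c(low, high)` on the
#'   cumulative dominant-direction baseline excursion, mm.
#' @param amplitude_ratios AP and LR amplitudes as fractions of CC.
#' @return list of [resp_trace()] objects; each carries its generating
#'   `waveform_spec` and true drift magnitude in `attr(, "spec")` and
#'   `meta`.
#' @export
generate_cohort <- function(n_traces = NULL,
                            population = NULL,
                            seed = 1L,
                            noise_sd_mm = 0.2,
                            drift_model = c("piecewise", "constant"),
                            segment_range_s = c(20, 60),
                            p_drift_down = 0.8,
                            baseline_range_mm = c(-8, 3),
                            amplitude_ratios = c(ap = 0.40, lr = 0.25)) {
  drift_model <- match.arg(drift_model)
  if (is.null(population) && is.null(n_traces))
    population <- sbrt_cohort_population()
  if (is.null(population)) {
    population <- list(amplitude_mean_mm = 10.1, amplitude_sd_mm = 2.2,
                       period_mean_s = 3.0, period_sd_s = 0.6,
                       duration_mean_s = 156, duration_sd_s = 25,
                       drift_cc_range = c(0.05, 0.75))
  }
  if (is.data.frame(population)) {
    rows <- population[rep(seq_len(nrow(population)), population$n_traces), ]
    rows$beam <- unlist(lapply(population$n_traces, seq_len))
  } else {
    if (is.null(n_traces) || n_traces < 1)
      stop("generate_cohort: 'n_traces' must be >= 1")
    p <- population
    rows <- data.frame(patient = 0L, location = NA_character_,
                       amplitude_mean_mm = p$amplitude_mean_mm,
                       amplitude_sd_mm = p$amplitude_sd_mm,
                       period_mean_s = p$period_mean_s,
                       period_sd_s = p$period_sd_s,
                       beam_time_mean_s = p$duration_mean_s,
                       beam_time_sd_s = p$duration_sd_s,
                       n_traces = n_traces)[rep(1L, n_traces), ]
    rows$beam <- seq_len(n_traces)
    rows$drift_lo <- p$drift_cc_range[1]
    rows$drift_hi <- p$drift_cc_range[2]
  }
  if (is.null(rows$drift_lo)) {
    bands <- t(vapply(rows$location, drift_band, numeric(2)))
    rows$drift_lo <- bands[, 1]
    rows$drift_hi <- bands[, 2]
  }
  m <- nrow(rows)

  with_seed(seed, {
    amp_cc <- draw_truncated_normal(m, rows$amplitude_mean_mm,
                                    rows$amplitude_sd_mm, 0.5)
    period <- draw_truncated_normal(m, rows$period_mean_s, rows$period_sd_s, 1.0)
    duration <- draw_truncated_normal(m, rows$beam_time_mean_s,
                                      rows$beam_time_sd_s, 60)
    drift_cc <- stats::runif(m, rows$drift_lo, rows$drift_hi)
    first_sign <- sample(c(-1, 1), m, replace = TRUE,
                         prob = c(p_drift_down, 1 - p_drift_down))
    trace_seed <- sample.int(.Machine$integer.max - 1L, m)
    seg_seed <- sample.int(.Machine$integer.max - 1L, m)

    lapply(seq_len(m), function(i) {
      rates <- drift_cc[i] * c(ap = 0.55, cc = 1, lr = 0.50)
      drift <- if (drift_model == "constant") {
        as.list(first_sign[i] * rates)
      } else {
        with_seed(seg_seed[i], {
          # biased random-direction segments in the dominant (CC) baseline,
          # reflected at the excursion bounds; other directions follow the
          # same sign pattern at their scaled rates
          t0 <- numeric(0); sgn <- numeric(0)
          t_cur <- 0; b <- 0
          s <- first_sign[i]
          while (t_cur < duration[i]) {
            len <- stats::runif(1, segment_range_s[1], segment_range_s[2])
            if (b <= baseline_range_mm[1]) s <- 1
            else if (b >= baseline_range_mm[2]) s <- -1
            # truncate the segment where the excursion bound is hit
            if (drift_cc[i] > 0) {
              to_cap <- if (s > 0) (baseline_range_mm[2] - b) / drift_cc[i]
                        else (b - baseline_range_mm[1]) / drift_cc[i]
              len <- min(len, max(to_cap, 1e-3))
            }
            t0 <- c(t0, t_cur); sgn <- c(sgn, s)
            b <- b + s * drift_cc[i] * len
            t_cur <- t_cur + len
            s <- sample(c(-1, 1), 1L,
                        prob = c(p_drift_down, 1 - p_drift_down))
          }
          lapply(rates, function(r) cbind(t_s = t0, rate = sgn * r))
        })
      }
      spec <- waveform_spec(
        duration_s = duration[i], sample_rate_hz = 30,
        base_amplitude_mm = amp_cc[i] * c(amplitude_ratios[["ap"]], 1,
                                          amplitude_ratios[["lr"]]),
        base_period_s = period[i],
        drift_rate_mm_per_s = drift,
        amplitude_cv = rows$amplitude_sd_mm[i] / rows$amplitude_mean_mm[i],
        period_cv = rows$period_sd_s[i] / rows$period_mean_s[i],
        noise_sd_mm = noise_sd_mm, seed = trace_seed[i])
      generate_trace(spec, meta = list(
        id = sprintf("p%02d_b%02d", rows$patient[i], rows$beam[i]),
        patient = rows$patient[i], beam = rows$beam[i],
        location = rows$location[i],
        drift_cc_mm_per_s = drift_cc[i]))
    })
  })
}
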