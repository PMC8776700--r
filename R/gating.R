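#' Gating window specifications
#'
#' A gating window is a set of non-overlapping fraction intervals in `[0, 1]`
#' of either the normalized cycle time (phase gating) or the normalized
#' amplitude (amplitude gating). Defaults follow common clinical 10-phase
#' sorting conventions: phase method -- expiration 35--65%, transition
#' 20--35% with 65--80%, inspiration 0--15% with 85--100%; amplitude method
#' -- expiration 0--30%, transition 35--65%, inspiration 70--100% of the
#' calibrated amplitude range.
#'
#' @param method `"phase"` or `"amplitude"`.
#' @param phase_name `"expiration"`, `"transition"` or `"inspiration"`.
#' @param intervals optional list of `c(lo, hi)` fraction pairs overriding
#'   the defaults; each must satisfy `0 <= lo < hi <= 1` and intervals must
#'   not overlap.
#' @return An object of class `gating_window`.
#' @export
gating_window <- function(method = c("phase", "amplitude"),
                          phase_name = c("expiration", "transition",
                                         "inspiration"),
                          intervals = NULL) {
  method <- match.arg(method)
  phase_name <- match.arg(phase_name)
  if (is.null(intervals)) {
    defaults <- list(
      phase = list(expiration = list(c(0.35, 0.65)),
                   transition = list(c(0.20, 0.35), c(0.65, 0.80)),
                   inspiration = list(c(0, 0.15), c(0.85, 1.0))),
      amplitude = list(expiration = list(c(0, 0.30)),
                       transition = list(c(0.35, 0.65)),
                       inspiration = list(c(0.70, 1.0))))
    intervals <- defaults[[method]][[phase_name]]
  }
  if (!is.list(intervals)) intervals <- list(intervals)
  for (iv in intervals) {
    if (length(iv) != 2 || !all(is.finite(iv)) ||
        iv[1] < 0 || iv[1] >= iv[2] || iv[2] > 1)
      stop("gating_window: each interval must satisfy 0 <= lo < hi <= 1")
  }
  if (length(intervals) > 1) {
    m <- do.call(rbind, intervals)
    m <- m[order(m[, 1]), , drop = FALSE]
    if (any(m[-nrow(m), 2] > m[-1, 1]))
      stop("gating_window: intervals must not overlap")
  }
  structure(list(method = method, phase_name = phase_name,
                 intervals = intervals),
            class = "gating_window")
}

#' @export
print.gating_window <- function(x, ...) {
  iv <- paste(vapply(x$intervals,
                     function(v) sprintf("[%.0f%%, %.0f%%]", 100 * v[1],
                                         100 * v[2]), character(1)),
              collapse = " + ")
  cat(sprintf("%s-gating window, %s phase: %s\n", x$method, x$phase_name, iv))
  invisible(x)
}

#' Assign respiratory phase and normalized amplitude to every sample
#'
#' Detects inspiration peaks in the gating direction and anchors phase 0 at
#' each peak; the phase fraction grows linearly in time to 1 at the next
#' peak, so the expiration trough of a symmetric waveform lands near phase
#' 0.5, bracketed by the 35--65% expiration window. Samples before the first
#' or at/after the last peak belong to no complete cycle and are flagged
#' out-of-cycle (excluded from gating). The amplitude fraction normalizes the
#' signal to the min/max observed during the first `n_calibration_cycles`
#' complete cycles -- the calibration a gating device performs once at the
#' start of a beam and never revisits -- and is deliberately not clipped to
#' `[0, 1]` when the signal later drifts outside the calibrated range.
#'
#' @param trace a [resp_trace()].
#' @param gating_direction direction of the gating signal (default `"cc"`).
#' @param sign `+1` if inspiration is the positive extreme.
#' @param n_calibration_cycles cycles used for amplitude calibration.
#' @param min_period_s,prominence_fraction,smooth_window_s peak-detection
#'   controls, as in [detect_expiration_points()].
#' @return An object of class `phase_assignment`: per-sample
#'   `phase_fraction` in `[0, 1)` (`NA` out of cycle), `amplitude_fraction`
#'   (may exceed `[0, 1]`; `NULL` when calibration was impossible),
#'   `cycle_index`, `in_cycle`, peak indices `anchors`, and `calibration`
#'   (`a_min`, `a_max` in gating coordinates, i.e. after applying `sign`).
#' @export
assign_phase <- function(trace, gating_direction = "cc", sign = 1,
                         n_calibration_cycles = 3,
                         min_period_s = NULL, prominence_fraction = 0.3,
                         smooth_window_s = 0) {
  stopifnot(inherits(trace, "resp_trace"))
  gating_direction <- direction_index(gating_direction)
  # inspiration peaks = expiration points of the inverted signal
  peaks <- detect_expiration_points(trace, gating_direction,
                                    min_period_s = min_period_s,
                                    prominence_fraction = prominence_fraction,
                                    sign = -sign,
                                    smooth_window_s = smooth_window_s)
  anchors <- peaks$idx
  if (length(anchors) < 2)
    stop("fewer than 2 inspiration peaks in trace '",
         if (is.null(trace$meta$id)) "<unnamed>" else trace$meta$id,
         "': cannot assign phase")
  n <- length(trace$time_s)
  t <- trace$time_s
  cyc <- findInterval(seq_len(n), anchors)
  in_cycle <- cyc >= 1L & seq_len(n) < anchors[length(anchors)]
  phase <- rep(NA_real_, n)
  i <- which(in_cycle)
  phase[i] <- (t[i] - t[anchors[cyc[i]]]) /
    (t[anchors[cyc[i] + 1L]] - t[anchors[cyc[i]]])
  cyc[!in_cycle] <- NA_integer_

  y <- sign * trace$pos[, gating_direction]
  calibration <- NULL
  amplitude_fraction <- NULL
  if (length(anchors) >= n_calibration_cycles + 1) {
    span <- anchors[1]:anchors[n_calibration_cycles + 1]
    a_min <- min(y[span]); a_max <- max(y[span])
    calibration <- list(a_min = a_min, a_max = a_max,
                        n_cycles = n_calibration_cycles)
    amplitude_fraction <- (y - a_min) / (a_max - a_min)
  }
  structure(list(phase_fraction = phase,
                 amplitude_fraction = amplitude_fraction,
                 cycle_index = cyc, in_cycle = in_cycle, anchors = anchors,
                 n_cycles = length(anchors) - 1L,
                 calibration = calibration,
                 gating_direction = gating_direction, sign = sign),
            class = "phase_assignment")
}

#' Calibrate the amplitude-gating range from the first cycles
#'
#' Min and max of the gating-direction signal over the first
#' `n_calibration_cycles` complete respiratory cycles (inspiration peak to
#' inspiration peak). These bounds stay fixed for the remainder of the beam:
#' the device does not re-calibrate when the baseline drifts.
#'
#' @inheritParams assign_phase
#' @return numeric `c(a_min_mm, a_max_mm)` in gating coordinates.
#' @export
calibrate_amplitude <- function(trace, gating_direction = "cc", sign = 1,
                                n_calibration_cycles = 3, ...) {
  pa <- assign_phase(trace, gating_direction, sign = sign,
                     n_calibration_cycles = n_calibration_cycles, ...)
  if (is.null(pa$calibration))
    stop("trace has fewer than ", n_calibration_cycles,
         " complete cycles: cannot calibrate amplitude gating")
  c(a_min_mm = pa$calibration$a_min, a_max_mm = pa$calibration$a_max)
}

#' Compute the beam-on mask for a gating window
#'
#' Phase method: beam on where the phase fraction lies in one of the window
#' intervals. Amplitude method: beam on where the normalized amplitude lies
#' in an interval; by default an interval touching 0 (or 1) is open-ended
#' below (above) the calibrated range, mimicking a gating device whose low
#' (high) threshold keeps gating when the target drifts past the calibration
#' extremes -- set `strict_bounds = TRUE` to gate strictly inside the
#' calibrated range. Out-of-cycle samples are always beam-off.
#'
#' @param assignment a [assign_phase()] result covering the trace.
#' @param window a [gating_window()].
#' @param strict_bounds logical; see Description.
#' @return An object of class `beam_on_mask`: logical `on` per sample,
#'   `duty_cycle` (beam-on fraction of all samples) and
#'   `duty_cycle_in_cycle` (beam-on fraction of in-cycle samples).
#' @export
compute_gating_mask <- function(assignment, window, strict_bounds = FALSE) {
  stopifnot(inherits(assignment, "phase_assignment"),
            inherits(window, "gating_window"))
  if (window$method == "phase") {
    f <- assignment$phase_fraction
  } else {
    if (is.null(assignment$amplitude_fraction))
      stop("assignment has no amplitude calibration; amplitude gating ",
           "requires at least n_calibration_cycles complete cycles")
    f <- assignment$amplitude_fraction
  }
  on <- rep(FALSE, length(f))
  for (iv in window$intervals) {
    lo <- iv[1]; hi <- iv[2]
    hit <- if (window$method == "amplitude" && !strict_bounds) {
      lo_ok <- if (lo == 0) TRUE else f >= lo
      hi_ok <- if (hi == 1) TRUE else f <= hi
      lo_ok & hi_ok
    } else f >= lo & f <= hi
    on <- on | (hit & !is.na(f))
  }
  on <- on & assignment$in_cycle
  structure(list(on = on,
                 duty_cycle = mean(on),
                 duty_cycle_in_cycle =
                   if (any(assignment$in_cycle))
                     sum(on) / sum(assignment$in_cycle) else NA_real_,
                 method = window$method, phase_name = window$phase_name),
            class = "beam_on_mask")
}

#' Residual target motion inside a gating window
#'
#' Per respiratory cycle and direction, the displacement of the target while
#' the beam is on: by default the range (max minus min) of the beam-on
#' positions of that cycle (`per_cycle = "range"`; `"sd"` and
#' `"max_from_first"` are available as alternative readings). Cycles with
#' fewer than 2 beam-on samples contribute 0 mm (a window occupied for at
#' most one sample admits no displacement) and are counted, unless
#' `empty_cycles = "exclude"`.
#'
#' @param trace a [resp_trace()].
#' @param mask a [compute_gating_mask()] result aligned with the trace.
#' @param assignment the [assign_phase()] result that produced `mask`
#'   (supplies cycle boundaries).
#' @param per_cycle displacement definition within a cycle; see Description.
#' @param empty_cycles `"zero"` (default) or `"exclude"`.
#' @return An object of class `residual_motion`: `per_cycle_mm` (cycles x 3
#'   matrix), `mean_mm` (per direction), `residual_3d_mm` (Euclidean norm of
#'   the per-direction means), `n_cycles`, `n_empty_cycles` and an
#'   `all_off` warning flag.
#' @export
compute_residual_motion <- function(trace, mask, assignment,
                                    per_cycle = c("range", "sd",
                                                  "max_from_first"),
                                    empty_cycles = c("zero", "exclude")) {
  stopifnot(inherits(trace, "resp_trace"), inherits(mask, "beam_on_mask"),
            inherits(assignment, "phase_assignment"))
  per_cycle <- match.arg(per_cycle)
  empty_cycles <- match.arg(empty_cycles)
  if (length(mask$on) != length(trace$time_s))
    stop("mask is not aligned with the trace")
  disp <- switch(per_cycle,
    range = function(p) diff(range(p)),
    sd = function(p) stats::sd(p),
    max_from_first = function(p) max(abs(p - p[1])))
  n_cyc <- assignment$n_cycles
  per <- matrix(0, n_cyc, 3, dimnames = list(NULL, c("ap", "cc", "lr")))
  empty <- logical(n_cyc)
  for (c_i in seq_len(n_cyc)) {
    sel <- which(mask$on & !is.na(assignment$cycle_index) &
                   assignment$cycle_index == c_i)
    if (length(sel) < 2) { empty[c_i] <- TRUE; next }
    per[c_i, ] <- apply(trace$pos[sel, , drop = FALSE], 2, disp)
  }
  keep <- if (empty_cycles == "exclude") !empty else rep(TRUE, n_cyc)
  all_off <- !any(mask$on)
  mean_mm <- if (any(keep)) colMeans(per[keep, , drop = FALSE])
             else c(ap = 0, cc = 0, lr = 0)
  if (all_off) {
    warning("beam-on mask is entirely off; residual motion is zero")
    mean_mm <- c(ap = 0, cc = 0, lr = 0)
  }
  structure(list(per_cycle_mm = per, mean_mm = mean_mm,
                 residual_3d_mm = sqrt(sum(mean_mm^2)),
                 n_cycles = sum(keep), n_empty_cycles = sum(empty),
                 per_cycle = per_cycle, all_off = all_off),
            class = "residual_motion")
}

#' @export
print.residual_motion <- function(x, ...) {
  cat(sprintf(
    "Residual motion over %d cycles (%d with <2 beam-on samples)\n",
    x$n_cycles, x$n_empty_cycles))
  cat(sprintf("  mean [mm]: AP %.2f, CC %.2f, LR %.2f;  3D %.2f\n",
              x$mean_mm["ap"], x$mean_mm["cc"], x$mean_mm["lr"],
              x$residual_3d_mm))
  invisible(x)
}

#' Compare phase and amplitude gating across all respiratory phases
#'
#' Runs both gating methods over the expiration, transition and inspiration
#' windows of one trace and tabulates the mean residual motion per direction
#' plus its 3D norm, together with the phase-minus-amplitude differences.
#'
#' @inheritParams assign_phase
#' @param windows optional named list `windows[[method]][[phase_name]]` of
#'   [gating_window()] objects overriding the defaults.
#' @param strict_bounds passed to [compute_gating_mask()].
#' @param ... further arguments to [compute_residual_motion()].
#' @return An object of class `gating_comparison`: `table` (data frame:
#'   method, phase, mean residual per direction, residual_3d_mm, duty_cycle)
#'   and `differences` (phase minus amplitude, per phase).
#' @export
compare_gating_methods <- function(trace, gating_direction = "cc", sign = 1,
                                   windows = NULL, strict_bounds = FALSE,
                                   n_calibration_cycles = 3,
                                   min_period_s = NULL,
                                   prominence_fraction = 0.3,
                                   smooth_window_s = 0, ...) {
  pa <- assign_phase(trace, gating_direction, sign = sign,
                     n_calibration_cycles = n_calibration_cycles,
                     min_period_s = min_period_s,
                     prominence_fraction = prominence_fraction,
                     smooth_window_s = smooth_window_s)
  phases <- c("expiration", "transition", "inspiration")
  rows <- list()
  for (method in c("phase", "amplitude")) {
    for (ph in phases) {
      w <- if (!is.null(windows)) windows[[method]][[ph]]
           else gating_window(method, ph)
      mask <- compute_gating_mask(pa, w, strict_bounds = strict_bounds)
      res <- suppressWarnings(compute_residual_motion(trace, mask, pa, ...))
      rows[[length(rows) + 1L]] <- data.frame(
        method = method, phase = ph,
        ap_mm = res$mean_mm["ap"], cc_mm = res$mean_mm["cc"],
        lr_mm = res$mean_mm["lr"], residual_3d_mm = res$residual_3d_mm,
        duty_cycle = mask$duty_cycle_in_cycle,
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  tab <- do.call(rbind, rows)
  ph_t <- tab[tab$method == "phase", ]
  am_t <- tab[tab$method == "amplitude", ]
  differences <- data.frame(
    phase = phases,
    ap_mm = ph_t$ap_mm - am_t$ap_mm, cc_mm = ph_t$cc_mm - am_t$cc_mm,
    lr_mm = ph_t$lr_mm - am_t$lr_mm,
    residual_3d_mm = ph_t$residual_3d_mm - am_t$residual_3d_mm,
    stringsAsFactors = FALSE)
  structure(list(table = tab, differences = differences,
                 trace_id = trace$meta$id),
            class = "gating_comparison")
}

#' @export
print.gating_comparison <- function(x, digits = 3, ...) {
  cat("Residual motion by gating method and respiratory phase [mm]\n")
  print(x$table, digits = digits, row.names = FALSE)
  cat("\nDifferences (phase - amplitude) [mm]\n")
  print(x$differences, digits = digits, row.names = FALSE)
  invisible(x)
}
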