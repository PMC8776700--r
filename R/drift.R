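#' Detect per-cycle expiration points
#'
#' Finds the end-expiration target position of each respiratory cycle in one
#' anatomical direction: local minima of the signal (under the convention
#' that inspiration is the positive extreme; set `sign = -1` for inverted
#' axes) subject to a minimum inter-minimum spacing and a minimum topographic
#' prominence relative to the global peak-to-peak range. Minima at the first
#' or last sample are never reported.
#'
#' For noisy signals two optional refinements are available: `smooth_window_s`
#' applies a zero-phase moving average before detection (detection only; the
#' reported amplitude comes from the raw signal), and `refine_window_s`
#' replaces the raw sample value at each detected trough with the mean of the
#' raw signal over a symmetric window around it, suppressing sample noise in
#' the expiration amplitude. The windowed mean adds a waveform-shape offset
#' that is constant across cycles and therefore cancels in the drift slope.
#'
#' @param trace a [resp_trace()].
#' @param direction `"ap"`, `"cc"` or `"lr"`.
#' @param min_period_s minimum separation between expiration points, seconds.
#'   Default: half the autocorrelation period estimate of the signal.
#' @param prominence_fraction minimum prominence as a fraction of the
#'   peak-to-peak range reference, in (0, 1].
#' @param prominence_reference `"windowed"` (default): the drift-robust
#'   [robust_range()] of the signal; `"global"`: the global peak-to-peak
#'   range. The two coincide on stationary signals; on drifting signals the
#'   global range is inflated by the net baseline excursion and can swallow
#'   every true trough, which is why the windowed reference is the default.
#' @param sign `+1` (default) if inspiration is the positive extreme in this
#'   direction, `-1` otherwise.
#' @param smooth_window_s zero-phase moving-average window used for
#'   detection, seconds (0 disables).
#' @param refine_window_s half-width of the trough-amplitude averaging
#'   window, seconds (0 disables; the raw sample value is used).
#' @return An object of class `expiration_series`: list with `direction`,
#'   `t_ep` (seconds, strictly increasing), `a_ep` (mm, native coordinates),
#'   `idx` (sample indices) and `constant_signal` flag. A constant signal
#'   yields an empty series with a warning.
#' @export
detect_expiration_points <- function(trace, direction = "cc",
                                     min_period_s = NULL,
                                     prominence_fraction = 0.3,
                                     prominence_reference = c("windowed",
                                                              "global"),
                                     sign = 1,
                                     smooth_window_s = 0,
                                     refine_window_s = 0) {
  prominence_reference <- match.arg(prominence_reference)
  stopifnot(inherits(trace, "resp_trace"))
  direction <- direction_index(direction)
  if (!sign %in% c(-1, 1)) stop("'sign' must be +1 or -1")
  if (prominence_fraction <= 0 || prominence_fraction > 1)
    stop("'prominence_fraction' must be in (0, 1]")
  dt <- trace_dt(trace)
  x_raw <- sign * trace$pos[, direction]
  rng <- diff(range(x_raw))
  empty <- function(flag) structure(
    list(direction = direction, t_ep = numeric(0), a_ep = numeric(0),
         idx = integer(0), sign = sign, constant_signal = flag),
    class = "expiration_series")
  if (rng == 0) {
    warning("constant signal in direction '", direction,
            "': no expiration points")
    return(empty(TRUE))
  }
  x_det <- x_raw
  if (smooth_window_s > 0) {
    k <- max(1L, round(smooth_window_s / dt))
    if (k %% 2L == 0L) k <- k + 1L
    if (k > 1L) {
      sm <- stats::filter(x_raw, rep(1 / k, k), sides = 2)
      x_det <- ifelse(is.na(sm), x_raw, as.numeric(sm))
    }
  }
  per <- estimate_period(x_det, dt)
  if (is.null(min_period_s))
    min_period_s <- if (is.na(per)) 0.5 else 0.5 * per
  if (min_period_s <= 0) stop("'min_period_s' must be > 0")
  range_ref <- if (prominence_reference == "global") diff(range(x_det))
               else robust_range(x_det, dt,
                                 period_s = if (is.na(per)) NULL else per)
  idx <- find_local_minima(x_det, min_distance = min_period_s / dt,
                           min_prominence = prominence_fraction * range_ref)
  if (!length(idx)) return(empty(FALSE))
  a <- x_raw[idx]
  if (refine_window_s > 0) {
    h <- max(1L, round(refine_window_s / dt))
    n <- length(x_raw)
    a <- vapply(idx, function(i)
      mean(x_raw[max(1L, i - h):min(n, i + h)]), numeric(1))
  }
  structure(list(direction = direction, t_ep = trace$time_s[idx],
                 a_ep = sign * a, idx = idx, sign = sign,
                 constant_signal = FALSE),
            class = "expiration_series")
}

#' Construct an expiration series directly
#'
#' Builds the per-cycle expiration-point container from explicit times and
#' amplitudes, e.g. for points obtained from an external tracking log.
#'
#' @param t_ep expiration times, seconds, strictly increasing.
#' @param a_ep expiration amplitudes, mm, same length.
#' @param direction `"ap"`, `"cc"` or `"lr"`.
#' @return an `expiration_series` as from [detect_expiration_points()].
#' @export
expiration_series <- function(t_ep, a_ep, direction = "cc") {
  direction <- direction_index(direction)
  if (length(t_ep) != length(a_ep))
    stop("'t_ep' and 'a_ep' must have the same length")
  if (length(t_ep) > 1 && any(diff(t_ep) <= 0))
    stop("'t_ep' must be strictly increasing")
  if (!all(is.finite(t_ep)) || !all(is.finite(a_ep)))
    stop("expiration points must be finite")
  structure(list(direction = direction, t_ep = as.numeric(t_ep),
                 a_ep = as.numeric(a_ep), idx = NA_integer_, sign = 1,
                 constant_signal = FALSE),
            class = "expiration_series")
}

#' @export
print.expiration_series <- function(x, ...) {
  cat(sprintf("Expiration series (%s): %d points\n", toupper(x$direction),
              length(x$t_ep)))
  if (length(x$t_ep) > 1)
    cat(sprintf("  median cycle %.2f s, amplitude span %.2f mm\n",
                stats::median(diff(x$t_ep)), diff(range(x$a_ep))))
  invisible(x)
}

#' Quantify baseline drift between consecutive expiration points
#'
#' The per-cycle baseline drift is the absolute slope between consecutive
#' end-expiration positions,
#' \deqn{\Delta_n = \frac{|A_{EP_{n+1}} - A_{EP_n}|}{t_{EP_{n+1}} - t_{EP_n}}
#' \quad [\mathrm{mm/s}],}
#' so it captures both how far the expiration target position shifts and how
#' quickly (one breathing cycle) it does so.
#'
#' @param series an `expiration_series` from [detect_expiration_points()].
#' @return An object of class `drift_profile`: list with `direction`,
#'   `delta_mm_per_s` (one value per consecutive pair, all >= 0), `t_mid`
#'   (pair midpoint times, for plotting/regression), and `summary` with
#'   `mean`, `max` and `p95` in mm/s. Fewer than 2 expiration points give an
#'   empty profile with `NA` summaries and `empty = TRUE`.
#' @export
compute_baseline_drift <- function(series) {
  stopifnot(inherits(series, "expiration_series"))
  n <- length(series$t_ep)
  if (n >= 2 && any(diff(series$t_ep) <= 0))
    stop("expiration times must be strictly increasing")
  if (n < 2) {
    return(structure(list(direction = series$direction,
                          delta_mm_per_s = numeric(0), t_mid = numeric(0),
                          summary = list(mean = NA_real_, max = NA_real_,
                                         p95 = NA_real_),
                          empty = TRUE),
                     class = "drift_profile"))
  }
  delta <- abs(diff(series$a_ep)) / diff(series$t_ep)
  structure(list(direction = series$direction,
                 delta_mm_per_s = delta,
                 t_mid = (series$t_ep[-n] + series$t_ep[-1]) / 2,
                 summary = list(mean = mean(delta), max = max(delta),
                                p95 = unname(stats::quantile(delta, 0.95))),
                 empty = FALSE),
            class = "drift_profile")
}

#' @export
print.drift_profile <- function(x, ...) {
  cat(sprintf("Baseline drift profile (%s): %d cycle pairs\n",
              toupper(x$direction), length(x$delta_mm_per_s)))
  if (!x$empty)
    cat(sprintf("  mean %.3f, max %.3f, p95 %.3f mm/s\n",
                x$summary$mean, x$summary$max, x$summary$p95))
  invisible(x)
}

#' Summarize drift profiles across beams
#'
#' Aggregates per-cycle drift values to per-profile (typically per-beam)
#' scalars and an overall per-direction summary. Both the per-beam mean and
#' max of the per-cycle drift are always reported; `aggregation` only selects
#' which is the headline column.
#'
#' @param profiles a `drift_profile` or list of them (e.g. one per beam).
#' @param aggregation `"mean"` (default) or `"max"`.
#' @return An object of class `drift_summary`: list with `per_profile` (data
#'   frame: direction, n_pairs, mean, max, p95, headline) and `overall` (data
#'   frame per direction: mean of headline, max of max). Profiles that are
#'   all empty give `overall = NULL` with `all_empty = TRUE`.
#' @export
summarize_drift <- function(profiles, aggregation = c("mean", "max")) {
  aggregation <- match.arg(aggregation)
  if (inherits(profiles, "drift_profile")) profiles <- list(profiles)
  if (!length(profiles)) stop("need at least one drift profile")
  per <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(direction = p$direction,
               n_pairs = length(p$delta_mm_per_s),
               mean = p$summary$mean, max = p$summary$max, p95 = p$summary$p95,
               stringsAsFactors = FALSE)
  }))
  per$headline <- per[[aggregation]]
  ok <- !is.na(per$headline)
  overall <- NULL
  if (any(ok)) {
    overall <- do.call(rbind, lapply(split(per[ok, ], per$direction[ok]),
      function(d) data.frame(direction = d$direction[1],
                             n_beams = nrow(d),
                             mean_headline = mean(d$headline),
                             max_headline = max(d$headline),
                             max_of_max = max(d$max),
                             stringsAsFactors = FALSE)))
    rownames(overall) <- NULL
  }
  structure(list(per_profile = per, overall = overall,
                 aggregation = aggregation, all_empty = !any(ok)),
            class = "drift_summary")
}

#' @export
print.drift_summary <- function(x, ...) {
  cat("Drift summary (headline = per-beam ", x$aggregation, " of per-cycle drift)\n",
      sep = "")
  if (x$all_empty) cat("  all profiles empty\n") else print(x$overall)
  invisible(x)
}
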