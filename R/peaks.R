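# Local-extremum detection with topographic prominence and minimum spacing.
#
# Contract (shared with the exhaustive test oracle):
#  1. Candidate minima are interior plateau runs strictly below both
#     neighbouring runs; the representative index is the plateau midpoint
#     (floor of the mean index). Runs touching the first or last sample are
#     excluded.
#  2. Prominence of a candidate i: walking left, let jL be the nearest index
#     with x[jL] < x[i] (0 if none); the left wall is max(x) over
#     (jL, i]; right side analogously. Prominence = min(left wall,
#     right wall) - x[i].
#  3. Candidates with prominence < min_prominence are dropped.
#  4. Spacing: survivors are visited by depth (smallest x first, ties by
#     index); a candidate within min_distance samples (|i - j| * dt <
#     min_period_s) of an already kept one is dropped.

local_minima_candidates <- function(x) {
  n <- length(x)
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nr <- length(r$values)
  if (nr < 3L) return(integer(0))
  j <- 2:(nr - 1L)
  is_min <- r$values[j] < r$values[j - 1L] & r$values[j] < r$values[j + 1L]
  keep <- j[is_min]
  keep <- keep[starts[keep] > 1L & ends[keep] < n]
  as.integer(floor((starts[keep] + ends[keep]) / 2))
}

minima_prominence <- function(x, idx) {
  vapply(idx, function(i) {
    v <- x[i]
    jl <- i - 1L
    lw <- -Inf
    while (jl >= 1L && x[jl] >= v) {
      if (x[jl] > lw) lw <- x[jl]
      jl <- jl - 1L
    }
    if (jl < 1L) lw <- max(x[seq_len(i)])
    jr <- i + 1L
    rw <- -Inf
    n <- length(x)
    while (jr <= n && x[jr] >= v) {
      if (x[jr] > rw) rw <- x[jr]
      jr <- jr + 1L
    }
    if (jr > n) rw <- max(x[i:n])
    min(lw, rw) - v
  }, numeric(1))
}

#' Find local minima with prominence and spacing constraints
#'
#' Plateau-aware local minima of a sampled signal, filtered to a minimum
#' topographic prominence and a minimum spacing, with deeper minima taking
#' priority. Endpoints are never returned.
#'
#' @param x numeric signal.
#' @param min_distance minimum index separation between reported minima.
#' @param min_prominence minimum prominence (same units as `x`).
#' @return integer vector of sample indices, increasing.
#' @export
find_local_minima <- function(x, min_distance = 1L, min_prominence = 0) {
  if (diff(range(x)) == 0) return(integer(0))
  cand <- local_minima_candidates(x)
  if (!length(cand)) return(integer(0))
  prom <- minima_prominence(x, cand)
  cand <- cand[prom >= min_prominence]
  if (!length(cand)) return(integer(0))
  ord <- cand[order(x[cand], cand)]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= min_distance))
      kept <- c(kept, i)
  }
  sort(kept)
}

#' Drift-robust peak-to-peak range estimate
#'
#' Median of the peak-to-peak ranges over consecutive windows of about two
#' respiratory periods. On a stationary signal this equals the global range;
#' on a signal with baseline drift it tracks the waveform amplitude instead
#' of the (drift-inflated) global excursion, making it the appropriate
#' reference for prominence thresholds.
#'
#' @param x numeric signal.
#' @param dt sampling step, seconds.
#' @param period_s window half-length, seconds; default is the
#'   autocorrelation period estimate (fallback 3 s).
#' @return range estimate in the units of `x`.
#' @export
robust_range <- function(x, dt, period_s = NULL) {
  if (is.null(period_s)) {
    period_s <- estimate_period(x, dt)
    if (is.na(period_s)) period_s <- 3
  }
  w <- max(2L, round(2 * period_s / dt))
  n <- length(x)
  if (n < 2L * w) return(diff(range(x)))
  starts <- seq(1L, n - w + 1L, by = w)
  stats::median(vapply(starts, function(s) diff(range(x[s:(s + w - 1L)])),
                       numeric(1)))
}

#' Estimate the dominant respiratory period by autocorrelation
#'
#' Returns the lag (seconds) of the global autocorrelation maximum beyond the
#' first zero crossing -- a robust cycle-length estimate for quasi-periodic
#' signals. The signal is linearly detrended first so that sustained baseline
#' drift (which otherwise dominates the autocorrelation of a strongly
#' drifting trace) does not masquerade as a long period. `NA` when no zero
#' crossing exists (e.g. a monotone signal).
#'
#' @param x numeric signal.
#' @param dt sampling step, seconds.
#' @param max_lag_s largest lag searched, seconds.
#' @return period estimate in seconds, or `NA`.
#' @export
estimate_period <- function(x, dt, max_lag_s = 15) {
  x <- stats::residuals(stats::lm.fit(cbind(1, seq_along(x)), x))
  n <- length(x)
  lag_max <- min(n - 2L, ceiling(max_lag_s / dt))
  if (lag_max < 2L) return(NA_real_)
  ac <- stats::acf(x, lag.max = lag_max, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  neg <- which(ac < 0)[1]
  if (is.na(neg) || neg >= lag_max) return(NA_real_)
  search <- ac[(neg + 1L):(lag_max + 1L)]
  peak <- which.max(search)
  if (search[peak] <= 0) return(NA_real_)
  (neg + peak - 1L) * dt
}
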