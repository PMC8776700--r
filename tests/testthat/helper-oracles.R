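# Independent brute-force oracles. These re-derive expected results by
# direct enumeration / dense-grid evaluation and deliberately share no code
# with the package internals they check.

# Exhaustive local-minimum scan: plateau runs strictly below both
# neighbouring runs (midpoint representative, endpoints excluded), walked
# prominence, prominence filter, then greedy spacing by depth.
oracle_local_minima <- function(x, min_distance, min_prominence) {
  n <- length(x)
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    j <- i
    while (j < n && x[j + 1L] == x[i]) j <- j + 1L
    if (x[i - 1L] > x[i] && j < n && x[j + 1L] > x[i]) {
      rep_idx <- as.integer(floor((i + j) / 2))
      if (i > 1L && j < n) cand <- c(cand, rep_idx)
    }
    i <- j + 1L
  }
  if (!length(cand)) return(integer(0))
  prom <- numeric(length(cand))
  for (k in seq_along(cand)) {
    ci <- cand[k]
    v <- x[ci]
    lw <- -Inf
    jl <- ci - 1L
    while (jl >= 1L && x[jl] >= v) {
      lw <- max(lw, x[jl])
      jl <- jl - 1L
    }
    if (jl < 1L) lw <- max(x[1:ci])
    rw <- -Inf
    jr <- ci + 1L
    while (jr <= n && x[jr] >= v) {
      rw <- max(rw, x[jr])
      jr <- jr + 1L
    }
    if (jr > n) rw <- max(x[ci:n])
    prom[k] <- min(lw, rw) - v
  }
  cand <- cand[prom >= min_prominence]
  if (!length(cand)) return(integer(0))
  ord <- cand[order(x[cand], cand)]
  kept <- integer(0)
  for (ci in ord) {
    ok <- TRUE
    for (kk in kept) if (abs(kk - ci) < min_distance) ok <- FALSE
    if (ok) kept <- c(kept, ci)
  }
  sort(kept)
}

# Closed-form noiseless waveform (cv = 0): constant drift per direction.
oracle_waveform <- function(t, amp, period, drift) {
  outer_t <- vapply(1:3, function(d)
    drift[d] * t + amp[d] * (1 - cos(2 * pi * t / period)) / 2,
    numeric(length(t)))
  colnames(outer_t) <- c("ap", "cc", "lr")
  outer_t
}

# Dense-grid gating oracle for a constant-drift, cv = 0, noiseless trace:
# evaluates the analytic waveform on a fine grid, rebuilds phase and
# amplitude gating from first principles and returns mean per-cycle
# in-window ranges per direction.
oracle_residual <- function(amp, period, drift, duration,
                            window_intervals, method,
                            dt_fine = 1 / 1200, n_cal = 3) {
  t <- seq(0, duration, by = dt_fine)
  pos <- oracle_waveform(t, amp, period, drift)
  y <- pos[, "cc"]
  n_cyc_total <- floor(duration / period)
  anchors <- integer(0)
  for (k in seq_len(n_cyc_total)) {
    sel <- which(t >= (k - 1) * period & t < k * period)
    anchors <- c(anchors, sel[which.max(y[sel])])
  }
  anchors <- anchors[anchors > 1 & anchors < length(t)]
  stopifnot(length(anchors) >= n_cal + 1)
  if (method == "phase") {
    frac <- rep(NA_real_, length(t))
    cyc <- rep(NA_integer_, length(t))
    for (j in seq_len(length(anchors) - 1L)) {
      sel <- anchors[j]:(anchors[j + 1L] - 1L)
      frac[sel] <- (t[sel] - t[anchors[j]]) /
        (t[anchors[j + 1L]] - t[anchors[j]])
      cyc[sel] <- j
    }
  } else {
    span <- anchors[1]:anchors[n_cal + 1]
    a_min <- min(y[span]); a_max <- max(y[span])
    frac <- (y - a_min) / (a_max - a_min)
    cyc <- rep(NA_integer_, length(t))
    for (j in seq_len(length(anchors) - 1L))
      cyc[anchors[j]:(anchors[j + 1L] - 1L)] <- j
  }
  on <- rep(FALSE, length(t))
  for (iv in window_intervals) {
    hit <- if (method == "amplitude") {
      lo_ok <- if (iv[1] == 0) TRUE else frac >= iv[1]
      hi_ok <- if (iv[2] == 1) TRUE else frac <= iv[2]
      lo_ok & hi_ok
    } else frac >= iv[1] & frac <= iv[2]
    on <- on | (hit & !is.na(frac))
  }
  on <- on & !is.na(cyc)
  n_cyc <- length(anchors) - 1L
  per <- matrix(0, n_cyc, 3, dimnames = list(NULL, c("ap", "cc", "lr")))
  for (j in seq_len(n_cyc)) {
    sel <- which(on & cyc == j)
    if (length(sel) >= 2)
      per[j, ] <- apply(pos[sel, , drop = FALSE], 2, function(p)
        diff(range(p)))
  }
  colMeans(per)
}

# Zero-padded integer shift of a 3-D array.
shift3 <- function(a, s) {
  d <- dim(a)
  out <- array(0, d)
  io <- lapply(1:3, function(ax) max(1L, 1L + s[ax]):min(d[ax], d[ax] + s[ax]))
  if (any(vapply(io, length, 1L) == 0L)) return(out)
  ii <- lapply(1:3, function(ax) io[[ax]] - s[ax])
  out[io[[1]], io[[2]], io[[3]]] <- a[ii[[1]], ii[[2]], ii[[3]]]
  out
}

# Direct (non-separable) 3-D convolution by exhaustive tap summation.
oracle_convolve3d <- function(arr, kernels) {
  out <- array(0, dim(arr))
  for (i in seq_along(kernels[[1]]$offsets))
    for (j in seq_along(kernels[[2]]$offsets))
      for (l in seq_along(kernels[[3]]$offsets)) {
        w <- kernels[[1]]$mass[i] * kernels[[2]]$mass[j] *
          kernels[[3]]$mass[l]
        out <- out + w * shift3(arr, c(kernels[[1]]$offsets[i],
                                       kernels[[2]]$offsets[j],
                                       kernels[[3]]$offsets[l]))
      }
  out
}

# Voxel-exhaustive DVH metric oracle: explicit loop over voxel centres.
oracle_dvh_metrics <- function(grid, center, diameter) {
  d <- dim(grid$dose_gy)
  rad <- diameter / 2
  doses <- numeric(0)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    xyz <- grid$origin_mm + (c(i, j, k) - 1) * grid$spacing_mm - center
    if (sum(xyz^2) <= rad^2)
      doses <- c(doses, grid$dose_gy[i, j, k])
  }
  s <- sort(doses)
  n <- length(s)
  q7 <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
  }
  list(D2 = q7(0.98), D98 = q7(0.02), D50 = q7(0.50), n = n)
}

# Discrete truncated-Gaussian position PDF on unit bins.
gaussian_pdf <- function(sigma_mm, half_support_mm, bin_width_mm = 1,
                         direction = "cc", shift_mm = 0) {
  centers <- seq(-half_support_mm, half_support_mm, by = bin_width_mm)
  mass <- exp(-(centers - shift_mm)^2 / (2 * sigma_mm^2))
  mass <- mass / sum(mass)
  structure(list(direction = direction,
                 bin_edges_mm = c(centers - bin_width_mm / 2,
                                  centers[length(centers)] + bin_width_mm / 2),
                 mass = mass, planned_mm = 0),
            class = "position_pdf")
}

# Single-bin (delta) PDF at an integer-bin displacement.
delta_pdf <- function(shift_mm = 0, bin_width_mm = 1, direction = "cc") {
  structure(list(direction = direction,
                 bin_edges_mm = shift_mm + c(-0.5, 0.5) * bin_width_mm,
                 mass = 1, planned_mm = 0),
            class = "position_pdf")
}
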