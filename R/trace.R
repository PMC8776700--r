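#' Respiratory trace objects
#'
#' A `resp_trace` holds a uniformly sampled intra-beam respiratory motion
#' record: target (fiducial-marker) position in millimetres along the three
#' anatomical axes -- anterior-posterior (`ap`), cranial-caudal (`cc`) and
#' left-right (`lr`) -- against time in seconds.
#'
#' @param time_s numeric vector of sample times, seconds, strictly increasing
#'   and uniformly spaced (relative step tolerance 1e-6).
#' @param ap_mm,cc_mm,lr_mm numeric vectors of positions, millimetres, same
#'   length as `time_s`, all finite.
#' @param meta named list of identifier strings (e.g. `patient`, `fraction`,
#'   `beam`, `id`). Free-form; carried through the analysis and into reports.
#'
#' @return An object of class `resp_trace`: a list with elements `time_s`
#'   (numeric), `pos` (numeric matrix, columns `ap`, `cc`, `lr`) and `meta`.
#' @export
resp_trace <- function(time_s, ap_mm, cc_mm, lr_mm, meta = list()) {
  time_s <- as.numeric(time_s)
  if (length(time_s) < 2L)
    stop("resp_trace: need at least 2 samples, got ", length(time_s))
  if (length(ap_mm) != length(time_s) || length(cc_mm) != length(time_s) ||
      length(lr_mm) != length(time_s))
    stop("resp_trace: position vectors must match length of 'time_s'")
  pos <- cbind(ap = as.numeric(ap_mm), cc = as.numeric(cc_mm),
               lr = as.numeric(lr_mm))
  if (!all(is.finite(time_s)) || !all(is.finite(pos)))
    stop("resp_trace: all times and positions must be finite")
  dt <- diff(time_s)
  if (any(dt <= 0))
    stop("resp_trace: 'time_s' must be strictly increasing")
  step <- stats::median(dt)
  if (any(abs(dt - step) > 1e-6 * step))
    stop("resp_trace: 'time_s' must be uniformly sampled ",
         "(relative tolerance 1e-6)")
  structure(list(time_s = time_s, pos = pos, meta = meta),
            class = "resp_trace")
}

#' @export
print.resp_trace <- function(x, ...) {
  n <- length(x$time_s)
  dt <- x$time_s[2] - x$time_s[1]
  cat("Respiratory trace", if (!is.null(x$meta$id)) paste0("'", x$meta$id, "'"),
      "\n")
  cat(sprintf("  %d samples, %.1f s at %.3g Hz\n", n,
              x$time_s[n] - x$time_s[1], 1 / dt))
  rng <- apply(x$pos, 2, function(p) diff(range(p)))
  cat(sprintf("  peak-to-peak range [mm]: AP %.2f, CC %.2f, LR %.2f\n",
              rng["ap"], rng["cc"], rng["lr"]))
  invisible(x)
}

#' @export
as.data.frame.resp_trace <- function(x, ...) {
  data.frame(time_s = x$time_s, ap_mm = x$pos[, "ap"],
             cc_mm = x$pos[, "cc"], lr_mm = x$pos[, "lr"])
}

#' @export
plot.resp_trace <- function(x, directions = c("ap", "cc", "lr"), ...) {
  directions <- match.arg(directions, c("ap", "cc", "lr"), several.ok = TRUE)
  old <- graphics::par(mfrow = c(length(directions), 1),
                       mar = c(3.5, 4, 1, 1))
  on.exit(graphics::par(old))
  for (d in directions) {
    graphics::plot(x$time_s, x$pos[, d], type = "l",
                   xlab = "time [s]", ylab = paste0(toupper(d), " [mm]"), ...)
  }
  invisible(x)
}

#' Sampling interval of a trace
#' @param trace a [resp_trace()].
#' @return sampling step in seconds.
#' @export
trace_dt <- function(trace) {
  stopifnot(inherits(trace, "resp_trace"))
  stats::median(diff(trace$time_s))
}

direction_index <- function(direction) {
  direction <- tolower(direction)
  if (!direction %in% c("ap", "cc", "lr"))
    stop("direction must be one of 'ap', 'cc', 'lr', got '", direction, "'")
  direction
}

#' Read and write respiratory trace CSV files
#'
#' The on-disk format is a UTF-8 CSV with header
#' `time_s,ap_mm,cc_mm,lr_mm`, one row per sample, decimal point. Positions
#' are written with 6 significant digits; times with 12, so that the uniform
#' time base survives the round trip for traces of any length. A write/read
#' round trip reproduces the trace at those precisions.
#'
#' @param path file path.
#' @return [read_trace_csv()] returns a [resp_trace()];
#'   [write_trace_csv()] returns `path` invisibly.
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("time_s", "ap_mm", "cc_mm", "lr_mm")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("trace file '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "))
  for (col in required) {
    v <- df[[col]]
    if (!is.numeric(v) || anyNA(v)) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(v))))[1]
      stop("trace file '", path, "': non-numeric value in column '", col,
           "' at data line ", bad)
    }
  }
  resp_trace(df$time_s, df$ap_mm, df$cc_mm, df$lr_mm,
             meta = list(id = sub("\\.csv$", "", basename(path)),
                         path = path))
}

#' @rdname read_trace_csv
#' @param trace a [resp_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "resp_trace"))
  df <- as.data.frame(trace)
  fmt <- c(time_s = "%.12g", ap_mm = "%.6g", cc_mm = "%.6g", lr_mm = "%.6g")
  out <- vapply(names(df), function(col) sprintf(fmt[[col]], df[[col]]),
                character(nrow(df)))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = ","), con)
  writeLines(apply(out, 1, paste, collapse = ","), con)
  invisible(path)
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
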