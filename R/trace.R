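#' Arterial blood-pressure trace objects
#'
#' A `bp_trace` holds one patient-channel time series on a uniform nominal
#' grid: timestamps `t` in seconds since record start, pressures `x` in mmHg,
#' and a logical `valid` mask (`FALSE` marks monitoring gaps). Invalid samples
#' keep their grid row so that binning and Fourier analysis can assume a
#' uniform 1 Hz grid throughout.
#'
#' @param x Numeric vector of pressures in mmHg. May contain `NA` at invalid
#'   positions.
#' @param fs Sampling rate in Hz (default 1, the bedside-numerics rate).
#' @param t Optional timestamps in seconds; defaults to `0, 1/fs, 2/fs, ...`.
#'   Must be strictly increasing with constant spacing `1/fs`.
#' @param valid Optional logical mask, same length as `x`; defaults to
#'   `is.finite(x)`.
#' @param patient_id,channel Identifiers; `channel` is one of `"SBP"`,
#'   `"DBP"`, `"MAP"`.
#' @return An object of class `bp_trace`.
#' @examples
#' tr <- bp_trace(c(120, 122, NA, 125), patient_id = "P01")
#' sum(tr$valid)
#' @export
bp_trace <- function(x, fs = 1, t = NULL, valid = NULL,
                     patient_id = "trace", channel = c("SBP", "DBP", "MAP")) {
  channel <- match.arg(channel)
  x <- as.numeric(x)
  n <- length(x)
  if (n == 0L) stop("`x` must contain at least one sample")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive sampling rate in Hz")
  }
  if (is.null(t)) t <- (seq_len(n) - 1) / fs
  if (length(t) != n) stop("`t` and `x` must have the same length")
  if (n > 1L) {
    dt <- diff(t)
    if (any(dt <= 0)) stop("`t` must be strictly increasing")
    if (any(abs(dt - 1 / fs) > 1e-6 / fs)) {
      stop("`t` must lie on a uniform grid with spacing 1/fs")
    }
  }
  if (is.null(valid)) valid <- is.finite(x)
  valid <- as.logical(valid)
  if (length(valid) != n) stop("`valid` must have the same length as `x`")
  valid <- valid & !is.na(valid)
  if (any(valid & !is.finite(x))) {
    stop("`x` must be finite wherever `valid` is TRUE")
  }
  new_bp_trace(t = t, x = x, valid = valid, patient_id = patient_id,
               channel = channel, fs = fs)
}

new_bp_trace <- function(t, x, valid, patient_id, channel, fs,
                         removed = NULL, diff_mask = NULL,
                         class = character()) {
  structure(
    list(t = t, x = x, valid = valid, patient_id = patient_id,
         channel = channel, fs = fs, removed = removed,
         diff_mask = diff_mask),
    class = c(class, "bp_trace")
  )
}

#' @export
print.bp_trace <- function(x, ...) {
  n <- length(x$x)
  dur <- n / x$fs
  cat(sprintf("<%s> %s/%s: %d samples at %g Hz (%.2f h), %d valid (%.1f%%)\n",
              paste(class(x)[1]), x$patient_id, x$channel, n, x$fs,
              dur / 3600, sum(x$valid), 100 * mean(x$valid)))
  if (!is.null(x$removed)) {
    cat(sprintf("  artifact-removed points: %d\n", sum(x$removed)))
  }
  if (!is.null(x$diff_mask)) {
    cat(sprintf("  masked successive differences: %d\n", sum(x$diff_mask)))
  }
  invisible(x)
}

#' Coerce to a bp_trace
#'
#' Numeric vectors become fully valid 1 Hz traces; traces pass through.
#' @param x A `bp_trace` or numeric vector.
#' @param ... Passed to [bp_trace()] for numeric input.
#' @return A `bp_trace`.
#' @export
as_bp_trace <- function(x, ...) {
  if (inherits(x, "bp_trace")) return(x)
  if (is.numeric(x)) return(bp_trace(x, ...))
  stop("cannot coerce object of class ", paste(class(x), collapse = "/"),
       " to bp_trace")
}

#' Maximal contiguous runs of valid samples
#'
#' @param trace A `bp_trace`.
#' @return Data frame with half-open index ranges `start`, `end`
#'   (1-based, `end` exclusive), one row per run.
#' @export
trace_segments <- function(trace) {
  trace <- as_bp_trace(trace)
  r <- rle(trace$valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep] + 1L)
}

#' Truncate a trace to its first hours of monitoring
#'
#' Keeps samples with `t - t[1] < hours * 3600`; a record shorter than the
#' requested duration is returned whole. Preprocessing annotations
#' (`removed`, `diff_mask`) are subset consistently.
#'
#' @param trace A `bp_trace`.
#' @param hours Monitoring duration to keep, in hours.
#' @return Trace of the same class, truncated.
#' @export
trace_truncate <- function(trace, hours) {
  trace <- as_bp_trace(trace)
  if (!is.numeric(hours) || length(hours) != 1L || hours <= 0) {
    stop("`hours` must be a single positive duration")
  }
  keep <- (trace$t - trace$t[1]) < hours * 3600
  trace_subset(trace, keep)
}

# subset by a leading logical/index window, keeping annotations aligned
trace_subset <- function(trace, keep) {
  idx <- which(keep)
  out <- trace
  out$t <- trace$t[idx]
  out$x <- trace$x[idx]
  out$valid <- trace$valid[idx]
  if (!is.null(trace$removed)) out$removed <- trace$removed[idx]
  if (!is.null(trace$diff_mask) && length(idx) >= 1L) {
    di <- idx[-length(idx)]  # diff i sits between samples i and i+1
    out$diff_mask <- if (length(di)) trace$diff_mask[di] else logical(0)
  }
  out
}

#' Read and write single-trace CSV files
#'
#' The on-disk format is one row per grid sample with columns `time_s`,
#' `sbp_mmhg` (or the channel's column name) and `valid` (0/1); invalid rows
#' are present with empty pressure, so the uniform grid is checkable.
#'
#' @param trace A `bp_trace`.
#' @param path File path.
#' @param patient_id,channel Identifiers used when reading.
#' @return `write_trace` returns `path` invisibly; `read_trace` a `bp_trace`.
#' @export
write_trace <- function(trace, path) {
  trace <- as_bp_trace(trace)
  df <- data.frame(time_s = trace$t,
                   sbp_mmhg = ifelse(trace$valid, trace$x, NA_real_),
                   valid = as.integer(trace$valid))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path, patient_id = basename(path), channel = "SBP") {
  df <- utils::read.csv(path)
  need <- c("time_s", "sbp_mmhg", "valid")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("malformed trace file ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  }
  if (nrow(df) < 1L) stop("malformed trace file ", path, ": no rows")
  dt <- if (nrow(df) > 1L) stats::median(diff(df$time_s)) else 1
  bp_trace(df$sbp_mmhg, fs = 1 / dt, t = df$time_s,
           valid = df$valid > 0, patient_id = patient_id, channel = channel)
}
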