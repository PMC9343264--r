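#' Moving-average threshold filter for artifact removal
#'
#' Compares every valid sample to the centered moving average of the other
#' valid samples within a `window_s`-second window and removes samples
#' deviating by more than `threshold_mmhg` from that average. Removed
#' points become gaps (their `valid` flag is cleared) and are recorded in
#' the `removed` mask. The candidate point is excluded from its own
#' reference average so a large spike cannot mask itself; a point with no
#' valid neighbours in the window is kept, since there is nothing to
#' compare it to.
#'
#' Intra-arterial 1 Hz numerics are contaminated by line flushes, blood
#' draws and transducer handling; these show up as short excursions far
#' from the local pressure level, which is what this filter targets. A
#' sustained genuine change (longer than the window) moves the average
#' with it and is retained.
#'
#' @param trace A `bp_trace`.
#' @param window_s Window length in seconds (default 61, i.e. +/-30 s of
#'   context at 1 Hz).
#' @param threshold_mmhg Removal threshold in mmHg (default 30).
#' @return A `clean_trace` (subclass of `bp_trace`) whose `valid` mask
#'   excludes removed points and whose `removed` field records them.
#' @export
threshold_filter <- function(trace, window_s = 61, threshold_mmhg = 30) {
  trace <- as_bp_trace(trace)
  if (!is.numeric(window_s) || length(window_s) != 1L || window_s <= 0) {
    stop("`window_s` must be a single positive window length in seconds")
  }
  if (!is.numeric(threshold_mmhg) || threshold_mmhg <= 0) {
    stop("`threshold_mmhg` must be positive")
  }
  v <- trace$valid
  if (!any(v)) stop("no valid samples")
  n <- length(trace$x)
  k <- max(1L, as.integer(floor(window_s * trace$fs / 2)))
  xv <- ifelse(v, trace$x, 0)
  cx <- cumsum(xv)
  cc <- cumsum(as.numeric(v))
  i <- seq_len(n)
  hi <- pmin(n, i + k)
  prev <- pmax(i - k, 1L) - 1L  # window [i-k, i+k], clipped to the record
  sum_prev <- cnt_prev <- numeric(n)
  pos <- prev >= 1L
  sum_prev[pos] <- cx[prev[pos]]
  cnt_prev[pos] <- cc[prev[pos]]
  win_sum <- cx[hi] - sum_prev
  win_cnt <- cc[hi] - cnt_prev
  # leave-one-out average of valid neighbours
  nb_sum <- win_sum - ifelse(v, trace$x, 0)
  nb_cnt <- win_cnt - as.numeric(v)
  avg <- ifelse(nb_cnt > 0, nb_sum / nb_cnt, NA_real_)
  removed <- v & !is.na(avg) & abs(trace$x - avg) > threshold_mmhg
  x <- trace$x
  x[removed] <- NA_real_
  new_bp_trace(t = trace$t, x = x, valid = v & !removed,
               patient_id = trace$patient_id, channel = trace$channel,
               fs = trace$fs, removed = removed,
               diff_mask = trace$diff_mask, class = "clean_trace")
}

#' Mask extreme successive differences
#'
#' Computes successive differences within contiguous valid runs (never
#' across gaps or removed artifacts), then masks differences whose
#' deviation from the per-patient mean difference exceeds three times the
#' per-patient SD of the differences. Masked differences are excluded from
#' ARV and SV sums downstream; the pressure values themselves are left
#' untouched. The criterion is applied once, on the original differences,
#' so re-running the operation cannot cascade.
#'
#' This guards ARV/SV against residual jump artifacts, in particular the
#' step discontinuities that artifact removal itself can create when a
#' run of samples is excised.
#'
#' @param trace A `clean_trace` (or any `bp_trace`).
#' @return The trace with its `diff_mask` field set: a logical vector of
#'   length `n - 1` where entry `i` refers to the difference
#'   `x[i+1] - x[i]`; `TRUE` marks an excluded difference.
#' @export
mask_extreme_diffs <- function(trace) {
  trace <- as_bp_trace(trace)
  n <- length(trace$x)
  if (sum(trace$valid) < 3L) stop("need at least 3 valid samples")
  mask <- rep(FALSE, max(0L, n - 1L))
  usable <- trace$valid[-n] & trace$valid[-1]
  d <- diff(trace$x)
  du <- d[usable]
  if (length(du) < 2L) {
    warning("fewer than 2 successive differences; nothing masked")
  } else {
    s <- stats::sd(du)
    if (s > 0) {
      mask[usable] <- abs(d[usable] - mean(du)) > 3 * s
    }
  }
  out <- trace
  out$diff_mask <- mask
  if (!inherits(out, "clean_trace")) {
    class(out) <- c("clean_trace", class(out))
    if (is.null(out$removed)) out$removed <- rep(FALSE, n)
  }
  out
}

#' Fill internal gaps by linear interpolation
#'
#' Replaces every invalid sample between the first and last valid samples
#' with the linear interpolant of the flanking valid values; leading and
#' trailing gaps are trimmed rather than extrapolated. Valid samples are
#' returned bit-identical. The result is a gap-free uniform series, the
#' input required by the spectral module; time-domain indices are computed
#' on non-interpolated data.
#'
#' @param trace A `bp_trace` or `clean_trace`.
#' @return A fully valid `bp_trace` (annotation masks dropped).
#' @export
interpolate_gaps <- function(trace) {
  trace <- as_bp_trace(trace)
  v <- trace$valid
  if (sum(v) < 2L) stop("need at least 2 valid samples to interpolate")
  first <- which.max(v)
  last <- length(v) + 1L - which.max(rev(v))
  idx <- first:last
  xi <- trace$x[idx]
  vi <- v[idx]
  if (!all(vi)) {
    fit <- stats::approx(trace$t[idx][vi], xi[vi], xout = trace$t[idx],
                         method = "linear")
    xi[!vi] <- fit$y[!vi]
  }
  new_bp_trace(t = trace$t[idx], x = xi, valid = rep(TRUE, length(idx)),
               patient_id = trace$patient_id, channel = trace$channel,
               fs = trace$fs)
}

#' Standard preprocessing pipeline for one trace
#'
#' Applies [threshold_filter()] then [mask_extreme_diffs()], the fixed
#' order used throughout: time-domain indices consume the result directly,
#' the spectral stage additionally passes it through [interpolate_gaps()].
#'
#' @param trace A `bp_trace`.
#' @inheritParams threshold_filter
#' @param verbose Emit a per-patient message with removal/mask counts.
#' @return A `clean_trace`.
#' @export
preprocess_trace <- function(trace, window_s = 61, threshold_mmhg = 30,
                             verbose = FALSE) {
  ct <- threshold_filter(trace, window_s = window_s,
                         threshold_mmhg = threshold_mmhg)
  ct <- mask_extreme_diffs(ct)
  if (verbose) {
    message(sprintf("%s: removed %d artifact points, masked %d differences",
                    ct$patient_id, sum(ct$removed), sum(ct$diff_mask)))
  }
  ct
}

#' @rdname preprocess_trace
#' @param cohort A `bp_cohort`.
#' @export
preprocess_cohort <- function(cohort, window_s = 61, threshold_mmhg = 30,
                              verbose = FALSE) {
  out <- lapply(cohort, function(p) {
    p$trace <- preprocess_trace(p$trace, window_s = window_s,
                                threshold_mmhg = threshold_mmhg,
                                verbose = verbose)
    p
  })
  structure(out, class = "bp_cohort")
}
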