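#' Downsample a trace by instantaneous sampling or bin averaging
#'
#' Partitions the record into half-open bins `[k*interval, (k+1)*interval)`
#' anchored at the record start and reduces each bin to one value by either
#' of the two schemes compared throughout this package:
#'
#' * `"instantaneous"` — keep the first valid sample in the bin and omit
#'   every other measurement, mimicking intermittent (e.g. cuff-style)
#'   sampling. High-frequency content aliases into the retained series at
#'   full amplitude.
#' * `"averaging"` — replace the bin by the arithmetic mean of its valid
#'   samples, exploiting the full-resolution record. Bin averaging acts as
#'   a low-pass filter (sinc-shaped response), suppressing content with
#'   period much shorter than the bin.
#'
#' @param trace A `bp_trace` or `clean_trace`.
#' @param interval_s Target sampling interval in seconds; must be at least
#'   the native interval `1/fs`.
#' @param method `"instantaneous"` or `"averaging"`.
#' @param min_frac For averaging: bins whose valid-sample count is below
#'   this fraction of the bin's grid positions are marked invalid
#'   (default 0.5), so gappy bins cannot contribute single-sample "means".
#' @return A `resampled_trace` (subclass of `bp_trace`) with bin-start
#'   timestamps, sampling rate `1/interval_s`, and a `valid` mask for bins
#'   with insufficient data.
#' @examples
#' tr <- bp_trace(1:300)
#' downsample(tr, 300, "averaging")$x      # 150.5
#' downsample(tr, 300, "instantaneous")$x  # 1
#' @export
downsample <- function(trace, interval_s,
                       method = c("averaging", "instantaneous"),
                       min_frac = 0.5) {
  trace <- as_bp_trace(trace)
  method <- match.arg(method)
  dt <- 1 / trace$fs
  if (!is.numeric(interval_s) || length(interval_s) != 1L ||
      interval_s < dt - 1e-9) {
    stop("`interval_s` must be a single interval >= the native interval 1/fs")
  }
  n <- length(trace$x)
  t0 <- trace$t[1]
  rel <- trace$t - t0
  duration <- n * dt
  nbins <- as.integer(ceiling(duration / interval_s - 1e-9))
  bin <- pmin(nbins - 1L, as.integer(floor(rel / interval_s + 1e-9)))
  v <- trace$valid
  grid_per_bin <- tabulate(bin + 1L, nbins)
  cnt <- tabulate((bin + 1L)[v], nbins)
  if (method == "averaging") {
    sums <- numeric(nbins)
    agg <- rowsum(trace$x[v], bin[v])
    sums[as.integer(rownames(agg)) + 1L] <- agg[, 1]
    xb <- ifelse(cnt > 0, sums / cnt, NA_real_)
    vb <- cnt >= min_frac * grid_per_bin & cnt > 0
  } else {
    xb <- rep(NA_real_, nbins)
    iv <- which(v)
    first <- iv[!duplicated(bin[iv])]  # first valid sample per bin
    xb[bin[first] + 1L] <- trace$x[first]
    vb <- cnt > 0
  }
  xb[!vb] <- NA_real_
  out <- new_bp_trace(t = t0 + (seq_len(nbins) - 1) * interval_s,
                      x = xb, valid = vb,
                      patient_id = trace$patient_id, channel = trace$channel,
                      fs = 1 / interval_s, class = "resampled_trace")
  out$interval_s <- interval_s
  out$method <- method
  out
}

#' Default sampling-interval grid for rate sweeps
#'
#' Spans intermittent-monitoring rates from the native 1 s up to 30 min,
#' including every time bin used for the per-index optimal settings (1, 2
#' and 5 min).
#'
#' @return Numeric vector of intervals in seconds.
#' @export
bpv_interval_grid <- function() {
  c(1, 5, 10, 30, 60, 120, 300, 600, 900, 1800)
}
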