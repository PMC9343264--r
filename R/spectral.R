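#' Analysis frequency bands for blood-pressure variability
#'
#' The four contiguous, non-overlapping bands used throughout: slower than
#' one cycle per 20 minutes ("low", diurnal variation and slow trends),
#' one per 20 to one per 5 minutes ("midrange"), one per 5 to one per
#' minute ("high"), and faster than one per minute up to the Nyquist
#' frequency ("very_high", dominated by measurement noise and fast
#' physiological fluctuation at 1 Hz).
#'
#' @param fs Sampling rate in Hz; the top band ends at the Nyquist
#'   frequency `fs/2`.
#' @return Data frame with columns `name`, `f_start`, `f_end` (Hz). Band
#'   membership of a DFT bin is half-open, `f_start <= f < f_end`, except
#'   that a band ending exactly at Nyquist includes the Nyquist bin.
#' @export
bpv_bands <- function(fs = 1) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive sampling rate")
  }
  if (fs / 2 <= 1 / 60) {
    stop("`fs` too low: Nyquist must exceed 1/60 Hz for the default bands")
  }
  data.frame(
    name = c("low", "midrange", "high", "very_high"),
    f_start = c(0, 1 / 1200, 1 / 300, 1 / 60),
    f_end = c(1 / 1200, 1 / 300, 1 / 60, fs / 2)
  )
}

validate_bands <- function(bands, nyquist) {
  need <- c("name", "f_start", "f_end")
  if (!is.data.frame(bands) || !all(need %in% names(bands))) {
    stop("`bands` must be a data frame with columns name, f_start, f_end")
  }
  if (any(bands$f_start < 0) || any(bands$f_start >= bands$f_end)) {
    stop("each band needs 0 <= f_start < f_end")
  }
  if (any(bands$f_end > nyquist + 1e-12)) {
    stop("band edges must not exceed the Nyquist frequency ", nyquist, " Hz")
  }
  bands
}

#' Band power of a uniform, gap-free pressure series
#'
#' Computes the discrete Fourier transform of the mean-subtracted series
#' and sums normalized squared magnitudes `|BPhat_k|^2 / N^2` over the DFT
#' bins whose frequency `f_k = k / (N * t_s)` falls in each band. The
#' summation is one-sided with positive-frequency bins doubled (the
#' Nyquist bin, when present, is not doubled), so that the total power
#' over all bands equals the population variance of the series
#' (Parseval); powers are in mmHg^2. The DC bin is excluded by mean
#' subtraction — the mean level is not variability. No window or taper is
#' applied and the series is transformed at its full length.
#'
#' @param series A fully valid `bp_trace` (e.g. from
#'   [interpolate_gaps()]) or a plain numeric vector.
#' @param bands Band definition data frame (default [bpv_bands()] at the
#'   series' sampling rate).
#' @param t_s Sampling interval in seconds, for numeric input
#'   (default 1).
#' @return An object of class `band_power`: a list with `power` (named
#'   numeric vector, mmHg^2), `n_samples`, `t_s`, `df` (frequency
#'   resolution `1/(N t_s)`, Hz) and `total_power_ex_dc`.
#' @examples
#' x <- 3 * sin(2 * pi * 4 * (0:511) / 512)  # on-bin sine, f = 4/512 Hz
#' bp <- band_power(x)
#' bp$power[["high"]]  # ~ 3^2 / 2
#' @export
band_power <- function(series, bands = NULL, t_s = 1) {
  if (inherits(series, "bp_trace")) {
    if (!all(series$valid)) {
      stop("series has gaps or removed samples; run interpolate_gaps() first")
    }
    x <- series$x
    t_s <- 1 / series$fs
  } else if (is.numeric(series)) {
    x <- as.numeric(series)
    if (anyNA(x)) stop("series has missing values; run interpolate_gaps() first")
  } else {
    stop("`series` must be a bp_trace or numeric vector")
  }
  N <- length(x)
  if (N < 4L) stop("need at least 4 samples for band power")
  nyq <- 1 / (2 * t_s)
  if (is.null(bands)) bands <- bpv_bands(1 / t_s)
  bands <- validate_bands(bands, nyq)

  y <- x - mean(x)
  X <- stats::fft(y)
  kmax <- N %/% 2L
  k <- seq_len(kmax)
  Pk <- (Mod(X[k + 1L]) / N)^2
  w <- rep(2, kmax)
  if (N %% 2L == 0L) w[kmax] <- 1  # Nyquist bin has no mirror
  fk <- k / (N * t_s)

  tol <- 1e-9 / (N * t_s)
  power <- numeric(nrow(bands))
  for (b in seq_len(nrow(bands))) {
    inb <- fk >= bands$f_start[b] - tol & fk < bands$f_end[b] - tol
    if (bands$f_end[b] >= nyq - tol) {
      inb <- inb | abs(fk - nyq) <= tol
    }
    power[b] <- sum(w[inb] * Pk[inb])
  }
  names(power) <- bands$name
  structure(list(power = power, n_samples = N, t_s = t_s,
                 df = 1 / (N * t_s),
                 total_power_ex_dc = sum(w * Pk),
                 bands = bands),
            class = "band_power")
}

#' @export
print.band_power <- function(x, ...) {
  cat(sprintf("Band power (N = %d, t_s = %g s, df = %.3g Hz)\n",
              x$n_samples, x$t_s, x$df))
  for (i in seq_along(x$power)) {
    cat(sprintf("  %-10s [%.6g, %.6g) Hz: %.4f mmHg^2\n",
                names(x$power)[i], x$bands$f_start[i], x$bands$f_end[i],
                x$power[i]))
  }
  cat(sprintf("  total (ex DC): %.4f mmHg^2\n", x$total_power_ex_dc))
  invisible(x)
}

#' Band power of a preprocessed trace
#'
#' Interpolates any internal gaps and computes [band_power()] on the
#' native full-resolution series — spectral power is always estimated at
#' the original 1 Hz resolution, not from downsampled data.
#'
#' @param trace A `clean_trace` (or `bp_trace`).
#' @param bands Optional band definition (default [bpv_bands()]).
#' @return A `band_power` object.
#' @export
spectral_battery <- function(trace, bands = NULL) {
  trace <- as_bp_trace(trace)
  band_power(interpolate_gaps(trace), bands = bands)
}
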