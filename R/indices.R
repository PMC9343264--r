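#' Time-domain blood-pressure-variability indices
#'
#' Computes the mean and the five BPV indices of a pressure series
#' `BP = (BP_1, ..., BP_n)`:
#'
#' * `sd`  — sample standard deviation,
#'   `sqrt( sum (BP_i - mean(BP))^2 / (n - 1) )`;
#' * `cv`  — coefficient of variation, `sd / mean` (requires `mean > 0`);
#' * `arv` — averaged real variability, the mean absolute successive
#'   difference `sum |BP_{i+1} - BP_i| / (n - 1)`;
#' * `sv`  — successive variation, the root-mean-square successive
#'   difference `sqrt( sum |BP_{i+1} - BP_i|^2 / (n - 1) )`;
#' * `tc`  — relative number of trend changes, the count of sign changes
#'   `(BP_{i+1} - BP_i) * (BP_{i+2} - BP_{i+1}) < 0` divided by `n`.
#'
#' Under gaps and artifact masking the `(n - 1)` denominators of ARV/SV are
#' replaced by the number of successive differences actually used: a
#' difference is used only when both samples are valid (same contiguous
#' segment — never across a gap) and the position is not excluded by the
#' trace's `diff_mask` (see [mask_extreme_diffs()]). TC counts sign changes
#' over triples of consecutive valid samples whose two differences are both
#' usable, and keeps the total valid sample count `n` as its denominator.
#' Zero products (flat steps) are not trend changes: the inequality is
#' strict. An index whose minimum sample count is not met is reported as
#' `NA`, never as 0 — zero is a meaningful variability value.
#'
#' @param series A `bp_trace`, `clean_trace`, `resampled_trace`, or plain
#'   numeric vector (treated as fully valid).
#' @param diff_mask Optional logical mask over difference positions
#'   (`TRUE` = exclude); defaults to the mask stored on the trace, if any.
#' @return An object of class `bpv_indices`: a list with fields `mean`,
#'   `sd`, `cv`, `arv`, `sv`, `tc`, `n` (valid sample count) and
#'   `n_diffs_used`.
#' @examples
#' unlist(compute_indices(c(1, 2, 3))[c("sd", "cv", "arv", "sv", "tc")])
#' compute_indices(c(100, 110, 100, 110))$tc  # 2 sign changes / n = 0.5
#' @export
compute_indices <- function(series, diff_mask = NULL) {
  tr <- as_bp_trace(series)
  if (is.null(diff_mask)) diff_mask <- tr$diff_mask
  v <- tr$valid
  n <- sum(v)
  if (n < 1L) stop("no valid samples")
  nn <- length(tr$x)
  xs <- tr$x[v]
  mu <- mean(xs)
  sdv <- if (n >= 2L) stats::sd(xs) else NA_real_
  cvv <- if (!is.na(sdv) && mu > 0) sdv / mu else NA_real_

  usable <- if (nn >= 2L) v[-nn] & v[-1L] else logical(0)
  if (!is.null(diff_mask)) {
    if (length(diff_mask) != nn - 1L) {
      stop("`diff_mask` must have length n - 1")
    }
    usable <- usable & !diff_mask
  }
  d_all <- if (nn >= 2L) diff(tr$x) else numeric(0)
  d <- d_all[usable]
  m <- length(d)
  arv <- if (n >= 2L && m >= 1L) mean(abs(d)) else NA_real_
  sv <- if (n >= 2L && m >= 1L) sqrt(mean(d^2)) else NA_real_

  tc <- NA_real_
  if (n >= 3L && nn >= 3L) {
    pair_ok <- usable[-(nn - 1L)] & usable[-1L]
    idx <- which(pair_ok)
    tc <- sum(d_all[idx] * d_all[idx + 1L] < 0) / n
  }

  structure(list(mean = mu, sd = sdv, cv = cvv, arv = arv, sv = sv,
                 tc = tc, n = n, n_diffs_used = m),
            class = "bpv_indices")
}

#' @export
print.bpv_indices <- function(x, ...) {
  cat(sprintf(
    "BPV indices (n = %d, diffs used = %d)\n  mean %.2f  sd %.3f  cv %.4f  arv %.3f  sv %.3f  tc %.4f\n",
    x$n, x$n_diffs_used, x$mean, x$sd, x$cv, x$arv, x$sv, x$tc))
  invisible(x)
}

#' Index battery over a grid of sampling intervals and methods
#'
#' Downsamples the trace to every requested `(interval, method)` pair and
#' computes the full index set for each, the per-patient ingredient of the
#' sampling-rate sweep. At the native interval the trace is used directly
#' (identity resampling), so its successive-difference mask applies; at
#' coarser intervals the bin series is a new sequence and no 1 s-level mask
#' carries over.
#'
#' @param trace A `clean_trace` (or `bp_trace`).
#' @param intervals Sampling intervals in seconds (default
#'   [bpv_interval_grid()]).
#' @param methods Downsampling methods to include.
#' @param min_frac Passed to [downsample()].
#' @return A data frame with one row per `(interval_s, method)` and columns
#'   `patient_id`, `channel`, `interval_s`, `method`, `mean`, `sd`, `cv`,
#'   `arv`, `sv`, `tc`, `n`, `n_diffs_used`.
#' @export
index_battery <- function(trace, intervals = bpv_interval_grid(),
                          methods = c("instantaneous", "averaging"),
                          min_frac = 0.5) {
  trace <- as_bp_trace(trace)
  methods <- match.arg(methods, several.ok = TRUE)
  native <- 1 / trace$fs
  rows <- list()
  for (interval in intervals) {
    for (method in methods) {
      ix <- if (abs(interval - native) < 1e-9) {
        compute_indices(trace)
      } else {
        compute_indices(downsample(trace, interval, method,
                                   min_frac = min_frac))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = trace$patient_id, channel = trace$channel,
        interval_s = interval, method = method,
        mean = ix$mean, sd = ix$sd, cv = ix$cv, arv = ix$arv, sv = ix$sv,
        tc = ix$tc, n = ix$n, n_diffs_used = ix$n_diffs_used)
    }
  }
  do.call(rbind, rows)
}
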