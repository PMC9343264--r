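#' Compare a per-patient statistic between outcome groups
#'
#' Two-sided Mann-Whitney U test with the effect size reported as the
#' area under the ROC curve: the probability that a randomly chosen
#' unfavorable-outcome patient has a larger value than a randomly chosen
#' favorable-outcome patient (ties count one half), computed exactly from
#' the rank-sum statistic as `AUC = U / (n1 * n2)`. The p-value uses exact
#' enumeration when the combined sample size is at most 20 and there are
#' no ties, and the tie-corrected normal approximation with continuity
#' correction otherwise. The 95% CI for the AUC is the distribution-based
#' Hanley-McNeil interval by default, with a stratified-bootstrap
#' alternative.
#'
#' @param favorable,unfavorable Numeric vectors of per-patient values;
#'   `NA`s (undefined indices) are dropped.
#' @param statistic Optional label stored in the result.
#' @param conf_level Confidence level for the AUC interval.
#' @param ci_method `"hanley-mcneil"` (closed form) or `"bootstrap"`
#'   (stratified resampling of both groups; seed the RNG for
#'   reproducibility).
#' @param n_boot Bootstrap resamples when `ci_method = "bootstrap"`.
#' @return A one-row data frame of class `cohort_comparison` with group
#'   sizes, group medians and quartiles, the U statistic (oriented
#'   unfavorable vs favorable), the two-sided `p_value`, `auc` and its CI.
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5))$auc  # perfect separation: 1
#' @export
compare_groups <- function(favorable, unfavorable, statistic = NA_character_,
                           conf_level = 0.95,
                           ci_method = c("hanley-mcneil", "bootstrap"),
                           n_boot = 2000) {
  ci_method <- match.arg(ci_method)
  favorable <- as.numeric(favorable[!is.na(favorable)])
  unfavorable <- as.numeric(unfavorable[!is.na(unfavorable)])
  n1 <- length(favorable)
  n2 <- length(unfavorable)
  if (n1 == 0L || n2 == 0L) {
    stop("both groups must contain at least one non-missing value")
  }
  U <- mw_u(unfavorable, favorable)
  auc <- U / (n1 * n2)
  pooled <- c(favorable, unfavorable)
  ties <- anyDuplicated(pooled) > 0L
  if (all(pooled == pooled[1])) {
    p <- 1  # no information: every assignment is rank-equivalent
  } else {
    exact <- (n1 + n2) <= 20L && !ties
    p <- stats::wilcox.test(unfavorable, favorable, alternative = "two.sided",
                            exact = exact, correct = TRUE)$p.value
    p <- min(p, 1)
  }

  ci <- switch(ci_method,
    "hanley-mcneil" = auc_ci_hanley(auc, n1, n2, conf_level),
    "bootstrap" = auc_ci_boot(favorable, unfavorable, conf_level, n_boot))

  q1 <- stats::quantile(favorable, c(0.25, 0.5, 0.75), names = FALSE)
  q2 <- stats::quantile(unfavorable, c(0.25, 0.5, 0.75), names = FALSE)
  structure(
    data.frame(statistic = statistic, n_favorable = n1, n_unfavorable = n2,
               median_favorable = q1[2], q25_favorable = q1[1],
               q75_favorable = q1[3],
               median_unfavorable = q2[2], q25_unfavorable = q2[1],
               q75_unfavorable = q2[3],
               U = U, p_value = p, auc = auc,
               auc_lo = ci[1], auc_hi = ci[2], ci_method = ci_method,
               stringsAsFactors = FALSE),
    class = c("cohort_comparison", "data.frame"))
}

# Mann-Whitney U for x vs y (number of pairs with x > y, ties counted 1/2),
# via midranks so tied observations are handled exactly
mw_u <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

auc_ci_hanley <- function(auc, n1, n2, conf_level) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se2 <- (auc * (1 - auc) + (n2 - 1) * (q1 - auc^2) +
            (n1 - 1) * (q2 - auc^2)) / (n1 * n2)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  half <- z * sqrt(max(se2, 0))
  c(max(0, auc - half), min(1, auc + half))
}

auc_ci_boot <- function(favorable, unfavorable, conf_level, n_boot) {
  n1 <- length(favorable)
  n2 <- length(unfavorable)
  reps <- vapply(seq_len(n_boot), function(i) {
    f <- favorable[sample.int(n1, n1, replace = TRUE)]
    u <- unfavorable[sample.int(n2, n2, replace = TRUE)]
    mw_u(u, f) / (n1 * n2)
  }, numeric(1))
  unname(stats::quantile(reps, c((1 - conf_level) / 2,
                                 1 - (1 - conf_level) / 2)))
}

#' Fisher's exact test for a 2x2 contingency table
#'
#' Two-sided exact p by hypergeometric enumeration, for the categorical
#' baseline comparisons accompanying the variability analysis.
#'
#' @param counts 2x2 matrix (or coercible) of non-negative integer counts.
#' @return The two-sided p-value.
#' @export
fisher_exact <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L))) stop("`counts` must be a 2x2 table")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("`counts` must contain non-negative integers")
  }
  stats::fisher.test(counts)$p.value
}

#' Sampling-frequency sweep of group separation
#'
#' For every `(interval, method, index)` cell, computes the per-patient
#' index via [index_battery()] and compares the outcome groups with
#' [compare_groups()], yielding the machine-readable p-value surface over
#' sampling rates: which index, at which rate and with which downsampling
#' scheme, separates favorable from unfavorable outcome.
#'
#' @param cohort A preprocessed `bp_cohort` (see [preprocess_cohort()]).
#' @param intervals,methods Grid to sweep (defaults: full interval grid,
#'   both methods).
#' @param indices Index columns to compare.
#' @param ... Passed to [compare_groups()] (e.g. `ci_method`).
#' @return A long data frame of class `sweep_result`: one
#'   `cohort_comparison` row per `(interval_s, method, index)`.
#' @export
frequency_sweep <- function(cohort,
                            intervals = bpv_interval_grid(),
                            methods = c("instantaneous", "averaging"),
                            indices = c("mean", "sd", "cv", "arv", "sv",
                                        "tc", "n"),
                            ...) {
  outcomes <- cohort_outcomes(cohort)
  check_two_groups(outcomes)
  batteries <- lapply(cohort_traces(cohort), index_battery,
                      intervals = intervals, methods = methods)
  tab <- do.call(rbind, batteries)
  rows <- list()
  for (interval in intervals) {
    for (method in methods) {
      cell <- tab[tab$interval_s == interval & tab$method == method, ]
      for (index in indices) {
        vals <- cell[[index]]
        cmp <- compare_groups(vals[outcomes == "favorable"],
                              vals[outcomes == "unfavorable"],
                              statistic = index, ...)
        cmp$interval_s <- interval
        cmp$method <- method
        rows[[length(rows) + 1L]] <- cmp
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Monitoring-duration sweep of group separation
#'
#' Truncates every record to its first `d` hours (patients with shorter
#' records contribute whatever they have), recomputes SD and SV at their
#' per-index optimal settings together with the four band powers, and
#' compares the groups — answering how early after thrombectomy the
#' variability signal becomes, and stays, predictive.
#'
#' @param cohort A preprocessed `bp_cohort`.
#' @param hours Durations to evaluate (default `1:24`).
#' @param sd_interval_s,sv_interval_s Averaging intervals for SD and SV
#'   (defaults: 2 min and 5 min, their optimal time bins).
#' @param bands Band definition for the spectral statistics.
#' @param ... Passed to [compare_groups()].
#' @return A long data frame of class `sweep_result` with a `duration_h`
#'   column; statistics are `sd_2min_avg`, `sv_5min_avg` and
#'   `power_<band>`.
#' @export
duration_sweep <- function(cohort, hours = 1:24,
                           sd_interval_s = 120, sv_interval_s = 300,
                           bands = NULL, ...) {
  outcomes <- cohort_outcomes(cohort)
  check_two_groups(outcomes)
  traces <- cohort_traces(cohort)
  sd_label <- sprintf("sd_%gmin_avg", sd_interval_s / 60)
  sv_label <- sprintf("sv_%gmin_avg", sv_interval_s / 60)
  rows <- list()
  for (d in hours) {
    vals <- lapply(traces, function(tr) {
      tt <- trace_truncate(tr, d)
      if (sum(tt$valid) < 4L) {
        return(stats::setNames(rep(NA_real_, 6),
                               c(sd_label, sv_label, "power_low",
                                 "power_midrange", "power_high",
                                 "power_very_high")))
      }
      sdv <- compute_indices(downsample(tt, sd_interval_s, "averaging"))$sd
      svv <- compute_indices(downsample(tt, sv_interval_s, "averaging"))$sv
      pw <- spectral_battery(tt, bands = bands)$power
      stats::setNames(c(sdv, svv, pw),
                      c(sd_label, sv_label, paste0("power_", names(pw))))
    })
    mat <- do.call(rbind, vals)
    for (statn in colnames(mat)) {
      cmp <- compare_groups(mat[outcomes == "favorable", statn],
                            mat[outcomes == "unfavorable", statn],
                            statistic = statn, ...)
      cmp$duration_h <- d
      rows[[length(rows) + 1L]] <- cmp
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

check_two_groups <- function(outcomes) {
  if (!any(outcomes == "favorable") || !any(outcomes == "unfavorable")) {
    stop("cohort must contain both favorable and unfavorable patients")
  }
  invisible(outcomes)
}
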