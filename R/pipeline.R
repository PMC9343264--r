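#' Configuration for a full pipeline run
#'
#' Collects every knob of the analysis with its default: preprocessing
#' (30 mmHg threshold, 61 s window), the sampling-interval grid, the four
#' frequency bands, the AUC CI method, and which sweeps to run. A
#' serialized `run_config` plus the input data and seeds fully determines
#' a run.
#'
#' Exactly one input source must be given: an in-memory `cohort`, a
#' `synth` configuration to simulate from, or an `input_dir` containing
#' per-patient CSVs and a `manifest.csv` (see [write_cohort()]).
#'
#' @param cohort Optional `bp_cohort`.
#' @param synth Optional [synth_config()].
#' @param input_dir Optional directory with a cohort on disk.
#' @param out_dir Output directory for the tidy CSVs and run log (`NULL`
#'   = keep results in memory only).
#' @param threshold_mmhg,window_s Preprocessing parameters.
#' @param intervals Sampling-interval grid for the index battery.
#' @param bands Frequency bands (default [bpv_bands()]).
#' @param ci_method AUC CI construction, see [compare_groups()].
#' @param sweeps Character subset of `c("frequency", "duration")`.
#' @param comparison_settings Named list mapping each index to its
#'   comparison time bin in seconds (the per-index optimal settings);
#'   comparisons use the averaging method.
#' @return A list of class `run_config`.
#' @export
run_config <- function(cohort = NULL, synth = NULL, input_dir = NULL,
                       out_dir = NULL,
                       threshold_mmhg = 30, window_s = 61,
                       intervals = bpv_interval_grid(),
                       bands = NULL,
                       ci_method = c("hanley-mcneil", "bootstrap"),
                       sweeps = character(),
                       comparison_settings = list(mean = 300, sd = 120,
                                                  cv = 60, tc = 120,
                                                  arv = 300, sv = 300)) {
  ci_method <- match.arg(ci_method)
  n_src <- sum(!is.null(cohort), !is.null(synth), !is.null(input_dir))
  if (n_src != 1L) {
    stop("config error: exactly one of `cohort`, `synth`, `input_dir` ",
         "must be provided")
  }
  if (!is.null(synth)) validate_synth_config(synth)
  bad <- setdiff(sweeps, c("frequency", "duration"))
  if (length(bad)) {
    stop("config error: unknown sweep(s) ", paste(bad, collapse = ", "))
  }
  structure(list(cohort = cohort, synth = synth, input_dir = input_dir,
                 out_dir = out_dir, threshold_mmhg = threshold_mmhg,
                 window_s = window_s, intervals = intervals, bands = bands,
                 ci_method = ci_method, sweeps = sweeps,
                 comparison_settings = comparison_settings),
            class = "run_config")
}

#' Run the full variability analysis
#'
#' Executes simulate-or-load, preprocessing, the time-domain index
#' battery, spectral band power, and group comparisons (plus any
#' requested sweeps), writing tidy CSVs and a run log when an output
#' directory is configured. Outcome labels are read only at the
#' comparison stage; preprocessing and index computation never see them.
#'
#' @param config A [run_config()].
#' @param verbose Log per-stage progress via `message()`.
#' @return A list of class `bpv_results` with elements `indices` (tidy
#'   per-patient battery), `spectrum` (tidy per-patient band power),
#'   `comparisons` (one `cohort_comparison` row per index at its
#'   comparison setting and per band), and optionally
#'   `frequency_sweep` / `duration_sweep`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  if (!inherits(config, "run_config")) stop("`config` must be a run_config")
  say <- function(...) if (verbose) message(sprintf(...))

  cohort <- if (!is.null(config$cohort)) {
    config$cohort
  } else if (!is.null(config$synth)) {
    say("simulating cohort (seed %d)", config$synth$seed)
    generate_cohort(config$synth)
  } else {
    say("loading cohort from %s", config$input_dir)
    read_cohort(config$input_dir)
  }
  outcomes <- cohort_outcomes(cohort)
  check_two_groups(outcomes)

  say("preprocessing %d traces (threshold %g mmHg, window %g s)",
      length(cohort), config$threshold_mmhg, config$window_s)
  clean <- preprocess_cohort(cohort, window_s = config$window_s,
                             threshold_mmhg = config$threshold_mmhg,
                             verbose = verbose)
  log_rows <- do.call(rbind, lapply(clean, function(p) {
    data.frame(patient_id = p$trace$patient_id,
               duration_h = length(p$trace$x) / p$trace$fs / 3600,
               n_valid = sum(p$trace$valid),
               n_removed = sum(p$trace$removed),
               n_diffs_masked = sum(p$trace$diff_mask))
  }))

  say("time-domain index battery over %d intervals", length(config$intervals))
  indices <- do.call(rbind, lapply(cohort_traces(clean), index_battery,
                                   intervals = config$intervals))

  say("spectral band power at native resolution")
  spectrum <- do.call(rbind, lapply(clean, function(p) {
    bp <- spectral_battery(p$trace, bands = config$bands)
    data.frame(patient_id = p$trace$patient_id, channel = p$trace$channel,
               band = names(bp$power), power_mmhg2 = unname(bp$power),
               n_samples = bp$n_samples, t_s = bp$t_s)
  }))

  say("group comparisons")
  fav <- outcomes == "favorable"
  cmp_rows <- list()
  for (index in names(config$comparison_settings)) {
    interval <- config$comparison_settings[[index]]
    cell <- indices[indices$interval_s == interval &
                      indices$method == "averaging", ]
    if (nrow(cell) == 0L) {
      warning("comparison interval ", interval, " s for `", index,
              "` is not on the configured grid; skipped")
      next
    }
    cmp <- compare_groups(cell[[index]][fav], cell[[index]][!fav],
                          statistic = sprintf("%s_%gmin_avg", index,
                                              interval / 60),
                          ci_method = config$ci_method)
    cmp_rows[[length(cmp_rows) + 1L]] <- cmp
  }
  for (band in unique(spectrum$band)) {
    v <- spectrum$power_mmhg2[spectrum$band == band]
    cmp <- compare_groups(v[fav], v[!fav],
                          statistic = paste0("power_", band),
                          ci_method = config$ci_method)
    cmp_rows[[length(cmp_rows) + 1L]] <- cmp
  }
  comparisons <- do.call(rbind, cmp_rows)

  results <- list(indices = indices, spectrum = spectrum,
                  comparisons = comparisons, log = log_rows)
  if ("frequency" %in% config$sweeps) {
    say("sampling-frequency sweep")
    results$frequency_sweep <- frequency_sweep(
      clean, intervals = config$intervals, ci_method = config$ci_method)
  }
  if ("duration" %in% config$sweeps) {
    say("monitoring-duration sweep")
    results$duration_sweep <- duration_sweep(
      clean, bands = config$bands, ci_method = config$ci_method)
  }
  class(results) <- "bpv_results"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) {
      utils::write.csv(df, file.path(config$out_dir, name),
                       row.names = FALSE, quote = FALSE)
    }
    wr(indices, "indices.csv")
    wr(spectrum, "spectrum.csv")
    wr(comparisons, "comparisons.csv")
    wr(log_rows, "run_log.csv")
    if (!is.null(results$frequency_sweep)) {
      wr(results$frequency_sweep, "frequency_sweep.csv")
    }
    if (!is.null(results$duration_sweep)) {
      wr(results$duration_sweep, "duration_sweep.csv")
    }
    say("results written to %s", config$out_dir)
  }
  results
}

#' @export
print.bpv_results <- function(x, ...) {
  cat(sprintf("<bpv_results> %d patients, %d index rows, %d band rows\n",
              nrow(x$log), nrow(x$indices), nrow(x$spectrum)))
  cat("comparisons:\n")
  cmp <- x$comparisons
  for (i in seq_len(nrow(cmp))) {
    cat(sprintf(
      "  %-20s median %6.3f vs %6.3f   p = %.3f  AUC = %.2f [%.2f, %.2f]\n",
      cmp$statistic[i], cmp$median_favorable[i], cmp$median_unfavorable[i],
      cmp$p_value[i], cmp$auc[i], cmp$auc_lo[i], cmp$auc_hi[i]))
  }
  invisible(x)
}
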