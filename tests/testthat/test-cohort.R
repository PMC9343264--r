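test_that("Mann-Whitney U, p and AUC match exhaustive enumeration", {
  cases <- list(
    list(f = c(1, 2, 3), u = c(4, 5)),
    list(f = c(1, 5, 2, 8), u = c(3, 9, 7)),
    list(f = c(2, 2, 4), u = c(2, 6, 1)),          # with ties
    list(f = rnorm(6), u = rnorm(5) + 1),
    list(f = c(10, 12, 9, 14, 11), u = c(13, 15, 8))
  )
  set.seed(61)
  for (cs in cases) {
    cmp <- compare_groups(cs$f, cs$u)
    ora <- oracle_mw(cs$f, cs$u)
    expect_equal(cmp$U, ora$U)
    expect_equal(cmp$auc, ora$U / (length(cs$f) * length(cs$u)))
    if (anyDuplicated(c(cs$f, cs$u)) == 0L) {
      expect_equal(cmp$p_value, ora$p, tolerance = 1e-12)
    }
  }
  # the documented small example: U = 6 of 6 possible pairs, p = 2/10
  cmp <- compare_groups(c(1, 2, 3), c(4, 5))
  expect_equal(cmp$U, 6)
  expect_equal(cmp$p_value, 0.2)
})

test_that("AUC is 0.5 for identical groups and 1 for separated groups", {
  same <- compare_groups(c(5, 7, 9), c(5, 7, 9))
  expect_equal(same$auc, 0.5)
  expect_equal(compare_groups(1:4, 5:9)$auc, 1.0)
  expect_equal(compare_groups(5:9, 1:4)$auc, 0.0)
})

test_that("AUC * n1 * n2 equals U exactly, ties counted one half", {
  set.seed(62)
  for (rep in 1:20) {
    f <- sample(1:10, sample(3:12, 1), replace = TRUE)
    u <- sample(1:10, sample(3:12, 1), replace = TRUE)
    cmp <- compare_groups(f, u)
    # direct pairwise count, the AUC's probabilistic definition
    pairs <- outer(u, f, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(cmp$auc * length(f) * length(u), sum(pairs))
    expect_equal(cmp$U, sum(pairs))
    expect_gte(cmp$auc, 0); expect_lte(cmp$auc, 1)
    expect_gt(cmp$p_value, 0); expect_lte(cmp$p_value, 1)
  }
})

test_that("AUC point estimate agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(63)
  f <- rnorm(10, 5)
  u <- rnorm(24, 6)
  cmp <- compare_groups(f, u)
  roc <- pROC::roc(response = rep(c(0, 1), c(10, 24)), predictor = c(f, u),
                   direction = "<", quiet = TRUE)
  expect_equal(cmp$auc, as.numeric(pROC::auc(roc)), tolerance = 1e-12)
})

test_that("Hanley-McNeil and bootstrap CIs bracket the AUC sensibly", {
  set.seed(64)
  f <- rnorm(12, 5)
  u <- rnorm(15, 5.8)
  hm <- compare_groups(f, u, ci_method = "hanley-mcneil")
  expect_true(hm$auc_lo <= hm$auc && hm$auc <= hm$auc_hi)
  expect_true(hm$auc_lo >= 0 && hm$auc_hi <= 1)
  bt <- compare_groups(f, u, ci_method = "bootstrap", n_boot = 500)
  expect_true(bt$auc_lo <= bt$auc + 0.05 && bt$auc_hi >= bt$auc - 0.05)
  expect_lt(abs((bt$auc_hi - bt$auc_lo) - (hm$auc_hi - hm$auc_lo)), 0.25)
})

test_that("empty or all-missing groups are rejected", {
  expect_error(compare_groups(numeric(0), 1:3), "at least one")
  expect_error(compare_groups(c(NA_real_, NA_real_), 1:3), "at least one")
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2)), 1.0)

  tab <- matrix(c(10, 0, 0, 10), 2)
  expect_equal(fisher_exact(tab), oracle_fisher(tab), tolerance = 1e-12)
  tab2 <- matrix(c(7, 2, 3, 8), 2)
  expect_equal(fisher_exact(tab2), oracle_fisher(tab2), tolerance = 1e-12)
  # row swap leaves the two-sided p unchanged
  expect_equal(fisher_exact(tab2), fisher_exact(tab2[2:1, ]), tolerance = 1e-12)
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("frequency sweep is consistent with direct comparison", {
  set.seed(65)
  mk <- function(offset, n) {
    lapply(seq_len(n), function(i) {
      x <- 130 + offset * (i %% 3) + cumsum(rnorm(600, 0, 0.5))
      list(trace = preprocess_trace(bp_trace(x)), outcome = NA)
    })
  }
  coh <- c(mk(0, 4), mk(2, 4))
  for (i in 1:4) coh[[i]]$outcome <- "favorable"
  for (i in 5:8) coh[[i]]$outcome <- "unfavorable"
  class(coh) <- "bp_cohort"

  sw <- frequency_sweep(coh, intervals = 60, methods = "averaging",
                        indices = "sv")
  expect_equal(nrow(sw), 1L)
  vals <- vapply(cohort_traces(coh), function(tr) {
    compute_indices(downsample(tr, 60, "averaging"))$sv
  }, numeric(1))
  direct <- compare_groups(vals[1:4], vals[5:8], statistic = "sv")
  expect_equal(sw$p_value, direct$p_value)
  expect_equal(sw$auc, direct$auc)
})

test_that("identical traces in both groups give null p-values", {
  x <- 130 + sin(2 * pi * (0:599) / 120)
  coh <- lapply(1:6, function(i) {
    list(trace = preprocess_trace(bp_trace(x)),
         outcome = if (i <= 3) "favorable" else "unfavorable")
  })
  class(coh) <- "bp_cohort"
  sw <- frequency_sweep(coh, intervals = c(1, 60), indices = c("sv", "sd"))
  expect_true(all(sw$p_value > 0.99))
  expect_true(all(abs(sw$auc - 0.5) < 1e-12))
})

test_that("duration sweep truncates correctly and matches the full analysis", {
  set.seed(66)
  coh <- lapply(1:8, function(i) {
    hrs <- if (i == 1) 2 else 3  # one patient has a short record
    x <- 130 + cumsum(rnorm(hrs * 3600, 0, 0.3)) +
      make_band_noise(hrs * 3600, 1 / 1200, 1 / 300, if (i <= 4) 2 else 4)
    list(trace = preprocess_trace(bp_trace(x)),
         outcome = if (i <= 4) "favorable" else "unfavorable")
  })
  class(coh) <- "bp_cohort"
  sw <- duration_sweep(coh, hours = c(2, 3))
  expect_s3_class(sw, "sweep_result")

  # at the full duration the sweep equals the untruncated analysis
  svs <- vapply(cohort_traces(coh), function(tr) {
    compute_indices(downsample(tr, 300, "averaging"))$sv
  }, numeric(1))
  direct <- compare_groups(svs[1:4], svs[5:8])
  row <- sw[sw$duration_h == 3 & sw$statistic == "sv_5min_avg", ]
  expect_equal(row$p_value, direct$p_value)
  expect_equal(row$auc, direct$auc)

  # the short-record patient contributes its whole record at both durations
  t1 <- trace_truncate(cohort_traces(coh)[[1]], 3)
  expect_equal(length(t1$x), 2 * 3600L)
})
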