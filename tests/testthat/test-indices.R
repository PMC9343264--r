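test_that("hand-computable series evaluate the index formulas exactly", {
  ix <- compute_indices(c(1, 2, 3))
  expect_equal(ix$mean, 2)
  expect_equal(ix$sd, 1)
  expect_equal(ix$cv, 0.5)
  expect_equal(ix$arv, 1)
  expect_equal(ix$sv, 1)
  expect_equal(ix$tc, 0)
  expect_equal(ix$n, 3L)

  ix <- compute_indices(c(100, 110, 100, 110))
  expect_equal(ix$arv, 10)
  expect_equal(ix$sv, 10)
  expect_equal(ix$tc, 2 / 4)  # two sign changes among three differences
  expect_equal(ix$n_diffs_used, 3L)
})

test_that("indices below their minimum sample count are NA, not zero", {
  ix <- compute_indices(42)
  expect_equal(ix$mean, 42)
  expect_true(is.na(ix$sd))
  expect_true(is.na(ix$arv))
  expect_true(is.na(ix$sv))
  expect_true(is.na(ix$tc))

  two <- compute_indices(c(1, 2))
  expect_false(is.na(two$sv))
  expect_true(is.na(two$tc))  # TC needs n >= 3
  # CV undefined for non-positive mean
  expect_true(is.na(compute_indices(c(-1, 0, 1))$cv))
})

test_that("differences never span gaps and masked diffs are excluded", {
  # segments (1,2,3) and (10,11): diffs used are 1,1,1 -> arv = 1, and the
  # 3 -> 10 change across the gap never enters
  tr <- bp_trace(c(1, 2, 3, NA, 10, 11))
  ix <- compute_indices(tr)
  expect_equal(ix$n_diffs_used, 3L)
  expect_equal(ix$arv, 1)
  expect_equal(ix$sv, 1)
  expect_equal(ix$n, 5L)

  # explicit diff_mask drops a difference from ARV/SV and from TC's triples
  x <- c(0, 1, 0, 1, 0)
  ix_all <- compute_indices(x)
  ix_m <- compute_indices(x, diff_mask = c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(ix_m$n_diffs_used, 3L)
  expect_equal(ix_m$arv, 1)
  expect_equal(ix_all$tc, 3 / 5)
  # masking diff 2 kills the triples (1,2,3) and (2,3,4): one change remains
  expect_equal(ix_m$tc, 1 / 5)
})

test_that("iid limits: TC -> 2/3, SV -> sigma*sqrt(2), ARV -> 2*sigma/sqrt(pi)", {
  set.seed(31)
  sigma <- 3
  x <- rnorm(1e5, 130, sigma)
  ix <- compute_indices(x)
  expect_equal(ix$tc, 2 / 3, tolerance = 0.01)
  expect_equal(ix$sv, sigma * sqrt(2), tolerance = 0.01)
  expect_equal(ix$arv, 2 * sigma / sqrt(pi), tolerance = 0.01)
})

test_that("SV >= ARV and scale/shift equivariance hold on random inputs", {
  set.seed(32)
  for (rep in 1:20) {
    n <- sample(5:200, 1)
    x <- 100 + cumsum(rnorm(n, 0, runif(1, 0.1, 5)))
    v <- runif(n) > 0.1
    if (sum(v) < 4) v[1:4] <- TRUE
    tr <- bp_trace(ifelse(v, x, NA), valid = v)
    ix <- compute_indices(tr)
    expect_gte(ix$sv, ix$arv - 1e-12)            # Cauchy-Schwarz
    expect_gte(ix$tc, 0)
    expect_lte(ix$tc, (ix$n - 2) / ix$n + 1e-12)

    c_ <- runif(1, 0.5, 3)
    sc <- compute_indices(bp_trace(ifelse(v, c_ * x, NA), valid = v))
    expect_equal(sc$sd, c_ * ix$sd, tolerance = 1e-10)
    expect_equal(sc$arv, c_ * ix$arv, tolerance = 1e-10)
    expect_equal(sc$sv, c_ * ix$sv, tolerance = 1e-10)
    expect_equal(sc$tc, ix$tc)

    sh <- compute_indices(bp_trace(ifelse(v, x + 37, NA), valid = v))
    expect_equal(sh$sd, ix$sd, tolerance = 1e-10)
    expect_equal(sh$arv, ix$arv, tolerance = 1e-10)
    expect_equal(sh$sv, ix$sv, tolerance = 1e-10)
    expect_equal(sh$tc, ix$tc)
  }
})

test_that("SV weights frequencies near the sampling rate more strongly", {
  # closed form: a unit sine of frequency f sampled at interval D has
  # SV = sqrt(2) * |sin(pi f D)| when the diffs cover whole cycles
  Delta <- 1
  freqs <- c(1, 3, 6, 12, 24, 48, 59) / 120  # below Nyquist, 4800 diffs
  svs <- vapply(freqs, function(f) {         # span whole difference cycles
    x <- sin(2 * pi * f * (0:4800) * Delta + 0.3)
    compute_indices(x)$sv
  }, numeric(1))
  expect_equal(svs, sqrt(2) * abs(sin(pi * freqs * Delta)), tolerance = 1e-9)
  expect_true(all(diff(svs) > 0))  # non-decreasing up to Nyquist
})

test_that("TC of a strictly monotone series is zero", {
  expect_equal(compute_indices(cumsum(runif(100, 0.1, 1)))$tc, 0)
})

test_that("index battery agrees with direct computation and handles constants", {
  flat <- preprocess_trace(bp_trace(rep(130, 4000)))
  bat <- index_battery(flat, intervals = c(1, 60, 300))
  expect_true(all(bat$sd == 0 & bat$arv == 0 & bat$sv == 0 & bat$tc == 0))

  set.seed(33)
  tr <- preprocess_trace(bp_trace(130 + cumsum(rnorm(4000, 0, 0.5))))
  bat <- index_battery(tr, intervals = c(1, 300))
  direct <- compute_indices(tr)
  row1 <- bat[bat$interval_s == 1 & bat$method == "averaging", ]
  expect_equal(row1$sv, direct$sv)
  expect_equal(row1$tc, direct$tc)
  expect_equal(row1$n_diffs_used, direct$n_diffs_used)
})

test_that("averaging crushes SV of high-frequency content; instantaneous keeps it", {
  set.seed(34)
  x <- 130 + make_band_noise(7200, 1 / 40, 1 / 4, 4)  # fast content only
  tr <- preprocess_trace(bp_trace(x))
  bat <- index_battery(tr, intervals = 300)
  sv_avg <- bat$sv[bat$method == "averaging"]
  sv_inst <- bat$sv[bat$method == "instantaneous"]
  expect_lt(sv_avg, 0.1 * sv_inst)
})
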