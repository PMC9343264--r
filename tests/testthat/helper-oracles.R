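# Independent reference implementations used as oracles. These are written
# deliberately naively (O(n*w), O(N^2), exhaustive enumeration) and share no
# code with the package internals they check.

# centered leave-one-out moving average of valid samples, brute force
oracle_moving_avg <- function(x, valid, window_s, fs = 1) {
  n <- length(x)
  k <- max(1L, as.integer(floor(window_s * fs / 2)))
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    idx <- max(1L, i - k):min(n, i + k)
    idx <- idx[idx != i & valid[idx]]
    if (length(idx)) out[i] <- mean(x[idx])
  }
  out
}

oracle_threshold_removed <- function(x, valid, window_s, threshold, fs = 1) {
  avg <- oracle_moving_avg(x, valid, window_s, fs)
  valid & !is.na(avg) & abs(x - avg) > threshold
}

# direct O(N^2) DFT band power, one-sided with doubling, mean-subtracted
oracle_band_power <- function(x, bands, t_s = 1) {
  N <- length(x)
  y <- x - mean(x)
  kmax <- N %/% 2L
  pw <- numeric(nrow(bands))
  nyq <- 1 / (2 * t_s)
  for (k in seq_len(kmax)) {
    re <- sum(y * cos(-2 * pi * k * (0:(N - 1)) / N))
    im <- sum(y * sin(-2 * pi * k * (0:(N - 1)) / N))
    Pk <- (re^2 + im^2) / N^2
    w <- if (N %% 2 == 0 && k == kmax) 1 else 2
    fk <- k / (N * t_s)
    for (b in seq_len(nrow(bands))) {
      hit <- fk >= bands$f_start[b] - 1e-12 && fk < bands$f_end[b] - 1e-12
      if (!hit && bands$f_end[b] >= nyq - 1e-12 && abs(fk - nyq) <= 1e-12) {
        hit <- TRUE
      }
      if (hit) pw[b] <- pw[b] + w * Pk
    }
  }
  stats::setNames(pw, bands$name)
}

# exhaustive Mann-Whitney: U for group2 vs group1 and the exact two-sided
# p-value 2 * min tail over all C(n1+n2, n2) group assignments
oracle_mw <- function(g1, g2) {
  u_stat <- function(a, b) {
    s <- 0
    for (ai in a) s <- s + sum(ai > b) + 0.5 * sum(ai == b)
    s
  }
  U <- u_stat(g2, g1)
  pool <- c(g1, g2)
  n <- length(pool)
  n2 <- length(g2)
  picks <- utils::combn(n, n2)
  us <- apply(picks, 2, function(ix) u_stat(pool[ix], pool[-ix]))
  p <- 2 * min(mean(us <= U), mean(us >= U))
  list(U = U, p = min(p, 1))
}

# two-sided Fisher exact p by hypergeometric enumeration over all tables
# with the observed margins
oracle_fisher <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# sum of K random-phase sinusoids confined to [f_lo, f_hi), SD sigma
make_band_noise <- function(n, f_lo, f_hi, sigma, K = 16) {
  f <- stats::runif(K, f_lo, f_hi)
  phi <- stats::runif(K, 0, 2 * pi)
  a <- sigma * sqrt(2 / K)
  t <- 0:(n - 1)
  x <- numeric(n)
  for (j in seq_len(K)) x <- x + a * cos(2 * pi * f[j] * t + phi[j])
  x
}
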