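# Brute-force reference implementations used as independent oracles.

# Scalar local-level Kalman filter, written as the literal predict/update
# recursion.
bf_kalman <- function(x, q, r, s0 = x[1], p0 = r) {
  s <- s0; p <- p0
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    pp <- p + q
    k <- pp / (pp + r)
    s <- s + k * (x[i] - s)
    p <- (1 - k) * pp
    out[i] <- s
  }
  out
}

# Trailing-window detrending by explicit per-sample window means.
bf_detrend <- function(x, rate, trend_window_s) {
  w <- floor(trend_window_s * rate) + 1
  vapply(seq_along(x), function(i) {
    x[i] - mean(x[max(1, i - w + 1):i])
  }, numeric(1))
}

# Percentile by explicit linear interpolation between order statistics
# (h = (n - 1) p + 1).
bf_percentile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Mann-Whitney AUC by exhaustive pairwise comparison, ties counted one half.
bf_auc <- function(means, labels, positive = "run") {
  pos <- means[labels == positive]
  neg <- means[labels != positive]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Five-line error metrics.
bf_rmse <- function(p, m) sqrt(sum((p - m)^2) / length(p))
bf_bias_rel <- function(p, m) sum((p - m) / m) / length(p)
bf_bias_abs <- function(p, m) sum(p - m) / length(p)
bf_loa <- function(p, m) {
  d <- p - m
  c(mean(d) - 1.96 * sd(d), mean(d) + 1.96 * sd(d))
}
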