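# Independent brute-force oracles used across tests. These are deliberately
# naive re-derivations (double loops, direct formulas) kept separate from the
# package implementations they check.

# type-7 percentile by explicit sort-and-interpolate
oracle_percentile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  if (lo == length(x)) return(x[lo])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# point-to-polyline distance by dense resampling of every segment
oracle_surface_distance <- function(px, py, sx, sy, n_samples = 1e4) {
  pts_x <- c(); pts_y <- c()
  for (s in seq_len(length(sx) - 1)) {
    t <- seq(0, 1, length.out = n_samples)
    pts_x <- c(pts_x, sx[s] + t * (sx[s + 1] - sx[s]))
    pts_y <- c(pts_y, sy[s] + t * (sy[s + 1] - sy[s]))
  }
  vapply(seq_along(px), function(i) {
    sqrt(min((pts_x - px[i])^2 + (pts_y - py[i])^2))
  }, numeric(1))
}

# exhaustive all-pairs nearest-TSS assignment with the lexicographic tie rule
oracle_assign <- function(peaks, genes) {
  out <- character(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    g <- genes[genes$chrom == peaks$chrom[i], ]
    if (nrow(g) == 0) { out[i] <- NA_character_; next }
    d <- abs((peaks$summit[i] + 1) - g$tss)
    cand <- g$gene_id[d == min(d)]
    out[i] <- min(cand)
  }
  out
}

# Benjamini-Hochberg step-up from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# 2x2 chi-square from the direct contingency formula (no continuity corr.)
oracle_chi2_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  expected <- outer(c(a + b, c + d), c(a + c, b + d)) / n
  obs <- matrix(c(a, c, b, d), 2)
  sum((obs - expected)^2 / expected)
}

# long-hand Welch statistic
oracle_welch <- function(xa, xb) {
  va <- var(xa) / length(xa); vb <- var(xb) / length(xb)
  t <- (mean(xa) - mean(xb)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(xa) - 1) + vb^2 / (length(xb) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# mean of a normal truncated to [lo, hi], by numerical integration
oracle_truncnorm_mean <- function(mu, sigma, lo, hi) {
  z <- integrate(function(x) dnorm(x, mu, sigma), lo, hi)$value
  integrate(function(x) x * dnorm(x, mu, sigma), lo, hi)$value / z
}
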