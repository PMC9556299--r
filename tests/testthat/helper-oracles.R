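# Independent oracles used across the suite.

# Exhaustive pairwise concordance (Mann-Whitney probability, ties = 1/2).
auc_pairwise <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Exact one-tailed rank-sum p-value by enumeration of all group assignments:
# P(rank sum of group b >= observed) under the null, for "b greater".
ranksum_exact_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  obs <- sum(r[seq_along(b) + length(a)])
  combos <- utils::combn(length(pooled), length(b))
  ge <- 0
  for (j in seq_len(ncol(combos))) {
    if (sum(r[combos[, j]]) >= obs) ge <- ge + 1
  }
  ge / ncol(combos)
}

# Exact one-tailed one-sample signed-rank p by enumeration of sign patterns.
signedrank_exact_p <- function(x, mu = 0) {
  d <- x - mu
  d <- d[d != 0]
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  n <- length(d)
  ge <- 0
  for (m in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(m))[seq_len(n)]
    if (sum(r[signs == 1]) >= obs) ge <- ge + 1
  }
  ge / 2^n
}

# Clopper-Pearson bounds found by bisection on the binomial tail.
cp_bisect <- function(x, n, conf = 0.95) {
  a <- (1 - conf) / 2
  f_lo <- function(p) 1 - pbinom(x - 1, n, p) - a   # P(X >= x) = a
  f_hi <- function(p) pbinom(x, n, p) - a           # P(X <= x) = a
  lo <- if (x == 0) 0 else uniroot(f_lo, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  hi <- if (x == n) 1 else uniroot(f_hi, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(lo, hi)
}

# Direct periodogram band powers: |FFT|^2 integrated over half-open bands.
periodogram_relpower <- function(x, fs) {
  n <- length(x)
  pw <- Mod(stats::fft(x))^2
  fr <- (seq_len(n) - 1) / n * fs
  keep <- seq_len(n %/% 2 + 1)
  pw <- pw[keep]; fr <- fr[keep]
  bands <- list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
                beta = c(13, 30))
  bp <- vapply(bands, function(be) sum(pw[fr >= be[1] & fr < be[2]]), numeric(1))
  bp / sum(bp)
}

tiny_cohort <- function(n_pd = 3L, n_control = 3L, nights = 2L,
                        night_hours = 1 / 30, seed = 7L, ...) {
  simulate_cohort(sim_config(n_pd = n_pd, n_control = n_control,
                             nights_per_subject = nights,
                             night_hours = night_hours, ...), seed = seed)
}
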