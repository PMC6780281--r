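# Independent brute-force oracles, coded from first principles and kept
# free of the package's implementations.

bf_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

bf_fisher_ci <- function(r, n, alpha = 0.05) {
  z <- 0.5 * log((1 + r) / (1 - r))
  hw <- qnorm(1 - alpha / 2) / sqrt(n - 3)
  (exp(2 * c(z - hw, z + hw)) - 1) / (exp(2 * c(z - hw, z + hw)) + 1)
}

bf_bland_altman <- function(ref, test) {
  d <- test - ref
  n <- length(d)
  bias <- sum(d) / n
  s <- sqrt(sum((d - bias)^2) / (n - 1))
  c(bias = bias, sd = s, lo = bias - 1.96 * s, hi = bias + 1.96 * s)
}

# nearest-neighbour delta pairing + exclusion zone, all via explicit loops
bf_concordance <- function(t, ref, test, interval, frac = 0.1, tol = 1,
                           mode = "both") {
  zone <- frac * sum(ref) / length(ref)
  n_used <- 0L; n_exc <- 0L; n_conc <- 0L
  for (i in seq_along(t)) {
    best <- NA_integer_; bestd <- Inf
    for (j in seq_along(t)) {
      d <- abs(t[j] - (t[i] + interval))
      if (d < bestd) { bestd <- d; best <- j }
    }
    if (bestd > tol || best <= i) next
    dr <- ref[best] - ref[i]; dt <- test[best] - test[i]
    inside <- if (mode == "both") abs(dr) < zone && abs(dt) < zone
              else abs(dr) < zone || abs(dt) < zone
    if (inside) { n_exc <- n_exc + 1L; next }
    n_used <- n_used + 1L
    if (sign(dr) == sign(dt)) n_conc <- n_conc + 1L
  }
  list(rate = if (n_used == 0) NA_real_ else 100 * n_conc / n_used,
       n_used = n_used, n_excluded = n_exc)
}

bf_median <- function(x) {
  s <- sort(x); n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

bf_performance_errors <- function(ref, test) {
  pe <- (ref - test) / test
  c(mdpe = bf_median(pe), mdape = bf_median(abs(pe)),
    rmse = sqrt(sum((ref - test)^2) / length(ref)))
}

# Steiger (1980) Z1* for dependent overlapping correlations, re-derived
bf_steiger <- function(r_jk, r_jh, r_kh, n) {
  zjk <- 0.5 * log((1 + r_jk) / (1 - r_jk))
  zjh <- 0.5 * log((1 + r_jh) / (1 - r_jh))
  rbar2 <- (r_jk^2 + r_jh^2) / 2
  f <- (1 - r_kh) / (2 * (1 - rbar2))
  if (f > 1) f <- 1
  h <- (1 - f * rbar2) / (1 - rbar2)
  z <- (zjk - zjh) * sqrt((n - 3) / (2 * (1 - r_kh) * h))
  c(z = z, p = 2 * (1 - pnorm(abs(z))))
}

# random strictly-positive paired series for property tests
random_pairs <- function(n, seed) {
  set.seed(seed)
  t <- cumsum(runif(n, 0.5, 3))
  ref <- pmax(rnorm(n, 85, 20), 5)
  test <- pmax(ref + rnorm(n, 2, 12), 5)
  paired_series(t, ref, test)
}
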