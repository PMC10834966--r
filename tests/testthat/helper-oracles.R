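# Independent brute-force oracles and small utilities shared by the tests.
# These are deliberately written as naive loops, separate from the package's
# vectorized implementations, so that agreement is a real cross-check.

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  do.call(c, lapply(seq_along(v), function(i) {
    lapply(all_perms(v[-i]), function(p) c(v[i], p))
  }))
}

# best average column-matching cosine similarity between two weight
# matrices, by exhaustive permutation search
best_matched_cosine <- function(W, W_true, worst = FALSE) {
  r <- ncol(W_true)
  agg <- if (worst) min else mean
  max(vapply(all_perms(seq_len(r)), function(p) {
    agg(vapply(seq_len(r), function(s) {
      cosine_sim(W[, p[s]], W_true[, s])
    }, numeric(1)))
  }, numeric(1)))
}

# naive Higuchi fractal dimension: explicit loops, no shared code
oracle_higuchi <- function(x, k_max = 10) {
  n <- length(x)
  logL <- c()
  logk <- c()
  for (k in 2:k_max) {
    tot <- 0
    for (t0 in 1:k) {
      m <- floor((n - t0) / k)
      s <- 0
      for (i in 1:m) s <- s + abs(x[t0 + i * k] - x[t0 + (i - 1) * k])
      tot <- tot + s * (n - 1) / (m * k) / k
    }
    logL <- c(logL, log(tot / k))
    logk <- c(logk, log(1 / k))
  }
  unname(coef(lm(logL ~ logk))[2])
}

# naive rescaled-range slope: explicit loop over halving prefixes
oracle_hurst <- function(x, q_inflex = 200) {
  n <- length(x)
  q <- n
  qs <- c()
  rss <- c()
  while (q >= 2) {
    h <- x[1:q]
    y <- cumsum(h - mean(h))
    rss <- c(rss, (max(y) - min(y)) / sd(h))
    qs <- c(qs, q)
    q <- floor(q / 2)
  }
  keep <- qs <= q_inflex
  unname(coef(lm(log(rss[keep]) ~ log(qs[keep])))[2])
}

# small noisy synthetic recording for quick tests
quick_recording <- function(n_cycles = 20, seed = 7, noise_sigma = 0.05,
                            ...) {
  generate_recording(default_truth(n_cycles = n_cycles, seed = seed,
                                   noise_sigma = noise_sigma, ...))
}
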