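# Independent oracles used to cross-check the package's own algorithms.
# These are deliberately naive (loops, brute force) and share no code with
# the implementation paths they validate.

# Exhaustive local-maxima scan with prominence, O(n^2): for every interior
# point that tops its neighbours, walk out to the nearest higher point on
# each side, record the minimum on the way, prominence = height - the larger
# of the two minima. Then greedy separation filter, tallest first.
brute_force_peaks <- function(y, min_prominence_frac, min_separation) {
  n <- length(y)
  peaks <- integer(0)
  for (i in 2:(n - 1)) {
    if (!(y[i] > y[i - 1] && y[i] >= y[i + 1])) next
    lmin <- y[i]
    for (j in (i - 1):1) {
      if (y[j] > y[i]) break
      lmin <- min(lmin, y[j])
    }
    rmin <- y[i]
    for (j in (i + 1):n) {
      if (y[j] > y[i]) break
      rmin <- min(rmin, y[j])
    }
    if (y[i] - max(lmin, rmin) >= min_prominence_frac * max(y)) {
      peaks <- c(peaks, i)
    }
  }
  if (!length(peaks)) return(integer(0))
  ord <- peaks[order(-y[peaks], peaks)]
  kept <- integer(0)
  for (p in ord) {
    if (!length(kept) || all(abs(p - kept) >= min_separation)) kept <- c(kept, p)
  }
  sort(kept)
}

# Discretized-Gaussian mean by direct summation (independent of the
# constructor's internals).
brute_force_disc_mean <- function(mean_lk, sd, half_support) {
  lk <- (round(mean_lk) - half_support):(round(mean_lk) + half_support)
  w <- exp(-(lk - mean_lk)^2 / (2 * sd^2))
  sum(lk * w) / sum(w)
}

# Permutation oracle for Tukey-style familywise pairwise p-values: the
# p-value for pair (i, j) is the share of label permutations whose maximum
# studentized pairwise statistic reaches the observed statistic of (i, j).
perm_tukey_oracle <- function(samples, B = 1e5, seed = 42) {
  x <- unlist(samples, use.names = FALSE)
  ns <- lengths(samples)
  k <- length(samples)
  n <- length(x)
  df <- n - k
  g <- rep(seq_len(k), ns)
  G <- outer(g, seq_len(k), "==") + 0    # n x k indicator
  pairs <- utils::combn(k, 2)
  se_fac <- sqrt(0.5 * (1 / ns[pairs[1, ]] + 1 / ns[pairs[2, ]]))

  q_of <- function(v) {
    m <- as.vector(crossprod(G, v)) / ns
    ssw <- sum(v^2) - sum(ns * m^2)
    mse <- ssw / df
    if (mse <= 0) return(rep(Inf, ncol(pairs)))
    abs(m[pairs[1, ]] - m[pairs[2, ]]) / (sqrt(mse) * se_fac)
  }
  q_obs <- q_of(x)
  set.seed(seed)
  qmax <- numeric(B)
  for (b in seq_len(B)) qmax[b] <- max(q_of(x[sample.int(n)]))
  p_hat <- vapply(q_obs, function(q) mean(qmax >= q), numeric(1))
  list(q_obs = q_obs, p_hat = p_hat,
       pairs = data.frame(group1 = names(samples)[pairs[1, ]],
                          group2 = names(samples)[pairs[2, ]]))
}
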