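# Independent brute-force oracles, deliberately naive implementations.

# O(n^2) nearest-neighbour distances with an explicit double loop.
brute_nn <- function(x, y) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
      if (d < best) best <- d
    }
    out[i] <- best
  }
  out
}

# Ordered-pair distance histogram on half-open bins [edges[k], edges[k+1]).
brute_pair_hist <- function(x, y, edges) {
  n <- length(x)
  counts <- numeric(length(edges) - 1)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
      for (k in seq_len(length(edges) - 1)) {
        if (d >= edges[k] && d < edges[k + 1]) {
          counts[k] <- counts[k] + 1
          break
        }
      }
    }
  }
  counts
}

# Exhaustive two-sided rank-sum p-value by enumerating every assignment of
# the pooled values into two groups of the observed sizes.
exhaustive_wilcox_p <- function(v1, v2) {
  pooled <- c(v1, v2)
  n1 <- length(v1)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  ws <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- mean(ws)
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

# Direct BH step-up: adjusted p_(i) = min over j >= i of m * p_(j) / j.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o]
  run_min <- Inf
  for (i in m:1) {
    run_min <- min(run_min, m * sorted[i] / i)
    adj[o[i]] <- min(run_min, 1)
  }
  adj
}

# One-way ANOVA F statistic from the textbook sums-of-squares formulas.
brute_anova_F <- function(values, groups) {
  groups <- as.character(groups)
  gm <- mean(values)
  lv <- split(values, groups)
  ss_between <- sum(vapply(lv, function(v) length(v) * (mean(v) - gm)^2, 1))
  ss_within <- sum(vapply(lv, function(v) sum((v - mean(v))^2), 1))
  df1 <- length(lv) - 1
  df2 <- length(values) - length(lv)
  (ss_between / df1) / (ss_within / df2)
}

std_window <- c(0, 0, 1000, 1000)
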