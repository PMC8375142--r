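# Independent oracles, written from first principles (binomial coefficients,
# exhaustive enumeration, closed forms) and never calling the implementation
# code paths they check.

# P(X >= k) for X ~ Hypergeom(N, K, n), by direct summation of the pmf
# computed from log binomial coefficients.
oracle_hyper_tail <- function(k, K, n, N) {
  if (k == 0) return(1)
  kk <- k:min(K, n)
  sum(exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)))
}

# Two-sided Fisher p for table rows (a, b) / (c, d): enumerate all tables
# with the observed margins and sum probabilities <= observed (with the
# classical relative tolerance for floating ties).
oracle_fisher_two_sided <- function(a, b, c, d) {
  m <- a + b; n_ <- c + d; k <- a + c; N <- m + n_
  lo <- max(0, k - n_); hi <- min(k, m)
  aa <- lo:hi
  logp <- lchoose(m, aa) + lchoose(n_, k - aa) - lchoose(N, k)
  p <- exp(logp)
  obs <- p[aa == a]
  min(1, sum(p[p <= obs * (1 + 1e-7)]))
}

# BH step-up by the direct formula: q_(i) = min_{j >= i} p_(j) * m / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

# Spearman as Pearson on mid-ranks.
oracle_spearman <- function(x, y) {
  stats::cor(rank(x), rank(y), method = "pearson")
}

# Brute-force UPGMA: at every step recompute every inter-cluster average
# distance exhaustively from the ORIGINAL distance matrix.
oracle_upgma <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  sizes_at_merge <- list()
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        avg <- mean(d[clusters[[i]], clusters[[j]]])
        if (avg < best_d) { best_d <- avg; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_d)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    sizes_at_merge[[length(heights)]] <- sort(merged)
    clusters <- c(clusters[-best], list(merged))
  }
  list(heights = heights, members = sizes_at_merge)
}

# members of the cluster created at merge step s of an hclust-style tree
cutree_members <- function(cl, s) {
  expand <- function(node) {
    if (node < 0) -node else c(expand(cl$merge[node, 1]), expand(cl$merge[node, 2]))
  }
  expand(s)
}

# Per-sample median by sort-and-pick.
oracle_median <- function(v) {
  s <- sort(v); n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}
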