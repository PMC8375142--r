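# Shared numerical primitives: exact tests, multiple-testing correction,
# rank correlation, average-linkage clustering with mean reordering, and PCA.

#' Upper-tail hypergeometric probability
#'
#' Probability of observing `k` or more successes when drawing `n` items
#' without replacement from a universe of `N` items of which `K` are
#' successes: `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. This is the
#' over-representation p-value used throughout the enrichment analyses.
#'
#' @param k Observed overlap (successes in the draw).
#' @param K Number of successes in the universe (e.g. gene-set size).
#' @param n Draw size (e.g. query-list size).
#' @param N Universe size.
#' @return A single p-value in (0, 1].
#' @examples
#' hypergeometric_tail(5, 5, 5, 10)  # 1 / choose(10, 5)
#' @export
hypergeometric_tail <- function(k, K, n, N) {
  stopifnot(length(k) == 1, length(K) == 1, length(n) == 1, length(N) == 1)
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n)) {
    evi_abort("invalid hypergeometric query: k=%s K=%s n=%s N=%s", k, K, n, N)
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Classical two-sided definition: the sum of probabilities, under fixed
#' margins, of all tables at most as probable as the observed one.
#'
#' @param a,b,c,d Cell counts, row-wise: `matrix(c(a, c, b, d), 2)`.
#' @return Two-sided p-value in (0, 1].
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    evi_abort("Fisher test requires non-negative integer counts")
  }
  if (sum(counts) < 1) evi_abort("Fisher test requires a non-empty table")
  stats::fisher.test(matrix(counts, nrow = 2, byrow = TRUE))$p.value
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment. Missing values are passed through as missing and
#' do not count towards the number of tests.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Adjusted p-values, original order, NA where input was NA.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) evi_abort("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Spearman correlation coefficient
#'
#' Pearson correlation of mid-ranks; ties receive mid-ranks. Returns NA with
#' a warning when either vector is constant (ranks undefined).
#'
#' @param x,y Equal-length numeric vectors, length >= 3.
#' @return Correlation in \[-1, 1\], or NA for constant input.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) evi_abort("vectors must have equal length")
  if (length(x) < 3) evi_abort("Spearman correlation needs >= 3 observations")
  suppressWarnings(stats::cor(x, y, method = "spearman"))
}

# 1 - Spearman distance between rows of a matrix; rows with zero variance get
# distance 1 to every other row (correlation undefined there).
spearman_distance <- function(m) {
  n <- nrow(m)
  const <- apply(m, 1, function(r) stats::sd(r) == 0 || all(!is.finite(r)))
  if (any(const)) {
    evi_warn("%d constant row(s); their correlation distance is set to 1", sum(const))
  }
  rk <- t(apply(m, 1, rank))
  cc <- suppressWarnings(stats::cor(t(rk)))
  d <- 1 - cc
  d[!is.finite(d)] <- 1
  d[const, ] <- 1
  d[, const] <- 1
  diag(d) <- 0
  d
}

#' UPGMA clustering with mean reordering
#'
#' Average-linkage (UPGMA) agglomerative clustering of matrix rows under a
#' 1 - Spearman-correlation distance, with deterministic tie-breaking
#' (the pair containing the lowest original row index wins). The leaf order
#' is produced by "mean reordering": at every internal node the subtree whose
#' member rows have the lower mean of row-means is placed first.
#'
#' @param x Numeric matrix (rows are clustered) or a full symmetric distance
#'   matrix when `is_distance = TRUE`.
#' @param is_distance Interpret `x` as a ready-made distance matrix.
#' @param row_means Per-row means used for mean reordering; defaults to
#'   `rowMeans(x)` (or zeros for distance input, which keeps input order
#'   among tied subtrees).
#' @return An object of class `c("upgma", "hclust")` with `merge`, `height`,
#'   `order` and `labels`, compatible with [stats::cutree()] and plotting.
#' @export
upgma_cluster <- function(x, is_distance = FALSE, row_means = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) evi_abort("clustering needs at least two rows")
  d <- if (is_distance) x else spearman_distance(x)
  if (is.null(row_means)) {
    row_means <- if (is_distance) rep(0, n) else rowMeans(x)
  }
  labels <- rownames(x) %||% as.character(seq_len(n))

  # active cluster bookkeeping; ids follow hclust convention
  # (-i = singleton i, +s = cluster formed at step s)
  id <- -seq_len(n)            # hclust id per active cluster
  size <- rep(1L, n)
  minleaf <- seq_len(n)        # lowest original row index, for tie-breaks
  members <- as.list(seq_len(n))
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  node_members <- vector("list", n - 1)
  node_children <- vector("list", n - 1)

  for (s in seq_len(n - 1)) {
    k <- length(id)
    # scan in order of lowest original leaf index for deterministic ties
    ord <- order(minleaf)
    best <- NULL
    best_d <- Inf
    for (ii in seq_len(k - 1)) {
      for (jj in (ii + 1):k) {
        i <- ord[ii]; j <- ord[jj]
        if (d[i, j] < best_d) {  # strict: first (lowest-index) pair wins ties
          best_d <- d[i, j]
          best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    pair <- c(id[i], id[j])
    # hclust row convention: singletons (negative) before clusters, each
    # ascending; within-row order is irrelevant to cutree/heights
    neg <- sort(pair[pair < 0], decreasing = TRUE)
    pos <- sort(pair[pair > 0])
    merge[s, ] <- c(neg, pos)[1:2]
    height[s] <- best_d
    node_members[[s]] <- c(members[[i]], members[[j]])
    node_children[[s]] <- c(id[i], id[j])

    # Lance-Williams update for UPGMA (size-weighted average)
    newd <- (size[i] * d[i, ] + size[j] * d[j, ]) / (size[i] + size[j])
    keep <- setdiff(seq_len(k), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    id <- c(id[keep], s)
    size <- c(size[keep], size[i] + size[j])
    minleaf <- c(minleaf[keep], min(minleaf[i], minleaf[j]))
    members <- c(members[keep], list(node_members[[s]]))
  }

  # mean reordering: lower subtree mean of row-means first; ties keep the
  # original child order
  subtree_leaves <- function(node) {
    if (node < 0) -node else node_members[[node]]
  }
  order_node <- function(node) {
    if (node < 0) return(-node)
    ch <- node_children[[node]]
    m1 <- mean(row_means[subtree_leaves(ch[1])])
    m2 <- mean(row_means[subtree_leaves(ch[2])])
    if (m2 < m1) ch <- ch[c(2, 1)]
    c(order_node(ch[1]), order_node(ch[2]))
  }
  leaf_order <- order_node(n - 1)

  structure(
    list(merge = merge, height = height, order = leaf_order,
         labels = labels, method = "average",
         call = match.call(), dist.method = "1 - spearman"),
    class = c("upgma", "hclust")
  )
}

#' Principal component analysis of samples
#'
#' Samples are projected onto principal components of the (optionally
#' log10(x + pseudocount) transformed) expression matrix after per-gene
#' mean-centering, via SVD. No unit scaling is applied.
#'
#' @param em Numeric genes x samples matrix.
#' @param log_transform Apply log10(x + pseudocount) first (default TRUE).
#' @param pseudocount Added before the log (default 1).
#' @return List with `scores` (data.frame, one row per sample, columns
#'   PC1..PCk) and `percent_var` (percent of variance per component,
#'   summing to 100).
#' @export
pca_samples <- function(em, log_transform = TRUE, pseudocount = 1) {
  if (ncol(em) < 2) evi_abort("PCA needs at least two samples")
  x <- if (log_transform) log10(em + pseudocount) else em
  fit <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  var <- fit$sdev^2
  pct <- 100 * var / sum(var)
  scores <- as.data.frame(fit$x)
  scores <- cbind(sample_id = colnames(em) %||% paste0("sample", seq_len(ncol(em))),
                  scores)
  rownames(scores) <- NULL
  list(scores = scores, percent_var = pct)
}
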