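test_that("hypergeometric upper tail matches the enumeration oracle", {
  # frozen examples: k = 0 gives 1; a single extreme outcome; an interior case
  expect_identical(hypergeometric_tail(0, 5, 5, 10), 1)
  expect_equal(hypergeometric_tail(5, 5, 5, 10), 1 / choose(10, 5),
               tolerance = 1e-14)
  expect_equal(hypergeometric_tail(3, 6, 5, 20), oracle_hyper_tail(3, 6, 5, 20),
               tolerance = 1e-13)
  # deterministic grid across small universes
  for (N in c(7, 13, 24, 41)) {
    for (K in unique(c(1, 3, N %/% 2, N - 1))) {
      for (n in unique(c(1, 2, N %/% 3, N %/% 2))) {
        for (k in 0:min(K, n)) {
          expect_equal(hypergeometric_tail(k, K, n, N),
                       oracle_hyper_tail(k, K, n, N), tolerance = 1e-12)
        }
      }
    }
  }
  expect_error(hypergeometric_tail(6, 5, 5, 10), "invalid")
  expect_error(hypergeometric_tail(1, 11, 5, 10), "invalid")
})

test_that("two-sided Fisher test matches the margin-enumeration oracle", {
  expect_equal(fisher_exact_two_sided(1, 1, 1, 1), 1)
  expect_equal(fisher_exact_two_sided(5, 0, 0, 5), 2 / choose(10, 5),
               tolerance = 1e-12)
  expect_equal(fisher_exact_two_sided(3, 1, 1, 3),
               oracle_fisher_two_sided(3, 1, 1, 3), tolerance = 1e-12)
  set.seed(42)
  for (i in 1:200) {
    tb <- as.vector(stats::rmultinom(1, sample(4:40, 1), rep(0.25, 4)))
    expect_equal(do.call(fisher_exact_two_sided, as.list(tb)),
                 do.call(oracle_fisher_two_sided, as.list(tb)),
                 tolerance = 1e-12)
  }
  expect_error(fisher_exact_two_sided(-1, 1, 1, 1), "non-negative")
  expect_error(fisher_exact_two_sided(0, 0, 0, 0), "non-empty")
})

test_that("BH adjustment matches the closed-form step-up and its properties", {
  expect_identical(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.02, 5)), rep(0.02, 5))
  p <- c(0.001, 0.01, 0.04, 0.5)
  expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-15)
  set.seed(1)
  for (i in 1:50) {
    p <- stats::runif(sample(2:60, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-14)
    # monotone, dominating, capped
    expect_true(all(q[order(p)] == cummax(q[order(p)])))
    expect_true(all(q >= p & q <= 1))
  }
  # missing values pass through and do not count as tests
  p <- c(0.01, NA, 0.02)
  expect_equal(bh_adjust(p), c(oracle_bh(c(0.01, 0.02)), NA)[c(1, 3, 2)])
  expect_error(bh_adjust(c(0.1, 1.5)), "\\[0, 1\\]")
})

test_that("Spearman correlation uses mid-ranks and is monotone-invariant", {
  expect_equal(spearman(1:6, (1:6)^3), 1, tolerance = 1e-12)
  expect_equal(spearman(1:6, rev(1:6)), -1, tolerance = 1e-12)
  x <- c(1, 2, 2, 3, 5, 5, 5)
  y <- c(2, 1, 4, 4, 6, 7, 7)
  expect_equal(spearman(x, y), oracle_spearman(x, y), tolerance = 1e-12)
  set.seed(2)
  for (i in 1:20) {
    x <- stats::rnorm(15); y <- stats::rnorm(15)
    s <- spearman(x, y)
    expect_equal(spearman(exp(x), y), s, tolerance = 1e-12)
    expect_equal(spearman(x, 3 * y - 7), s, tolerance = 1e-12)
  }
  expect_error(spearman(1:3, 1:4), "equal length")
  expect_error(spearman(1:2, 1:2), ">= 3")
})

test_that("UPGMA clustering matches the brute-force oracle and hclust", {
  set.seed(3)
  for (i in 1:25) {
    n <- sample(4:7, 1)
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- stats::runif(n * (n - 1) / 2)
    d <- d + t(d)
    cl <- upgma_cluster(d, is_distance = TRUE)
    or <- oracle_upgma(d)
    expect_equal(cl$height, or$heights, tolerance = 1e-12)
    # same clusters form at every step
    for (s in seq_len(n - 1)) {
      members <- sort(cutree_members(cl, s))
      expect_identical(members, or$members[[s]])
    }
    # independent cross-check against average-linkage hclust heights
    h <- stats::hclust(stats::as.dist(d), method = "average")
    expect_equal(sort(cl$height), sort(h$height), tolerance = 1e-12)
    # ultrametric: non-decreasing heights; leaf order is a permutation
    expect_true(all(diff(cl$height) >= -1e-12))
    expect_setequal(cl$order, seq_len(n))
  }
})

test_that("UPGMA handles zero distances, constant rows and ties deterministically", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4),
             c = c(4, 3, 2, 1), d = c(2, 1, 4, 3))
  cl <- upgma_cluster(m)
  expect_equal(cl$height[1], 0)          # identical rows merge first, height 0
  expect_identical(sort(cutree_members(cl, 1)), c(1L, 2L))
  # constant rows get distance 1 with a warning, clustering stays total
  m2 <- rbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(3, 2, 1))
  expect_warning(cl2 <- upgma_cluster(m2), "constant")
  expect_length(cl2$height, 2)
  # ties broken by lowest leaf index: equidistant singletons
  d <- matrix(1, 4, 4); diag(d) <- 0
  cl3 <- upgma_cluster(d, is_distance = TRUE)
  expect_identical(sort(cutree_members(cl3, 1)), c(1L, 2L))
  expect_error(upgma_cluster(m[1, , drop = FALSE]), "two rows")
})

test_that("mean reordering puts the lower-mean subtree first", {
  m <- rbind(lo = c(1, 1, 2), lo2 = c(1, 2, 1), hi = c(8, 9, 8), hi2 = c(9, 8, 9))
  cl <- upgma_cluster(m)
  om <- rowMeans(m)[cl$order]
  # the first leaf belongs to the lower-mean subtree at the root
  expect_true(om[1] < om[length(om)])
  # deterministic given input order
  cl2 <- upgma_cluster(m)
  expect_identical(cl$order, cl2$order)
})

test_that("sample PCA decomposes variance and matches an SVD oracle", {
  set.seed(4)
  em <- matrix(stats::runif(60, 0, 50), 10, 6,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  p <- pca_samples(em)
  expect_equal(sum(p$percent_var), 100, tolerance = 1e-6)
  # duplicated sample columns score identically
  em2 <- cbind(em, s7 = em[, 3])
  p2 <- pca_samples(em2)
  expect_equal(unlist(p2$scores[3, -1]), unlist(p2$scores[7, -1]),
               tolerance = 1e-8, ignore_attr = TRUE)
  # 3 x 3 toy against a direct SVD oracle, up to sign
  em3 <- matrix(c(1, 4, 9, 2, 3, 7, 8, 1, 5), 3, 3,
                dimnames = list(NULL, c("a", "b", "c")))
  x <- scale(t(log10(em3 + 1)), center = TRUE, scale = FALSE)
  sv <- svd(x)
  oracle_scores <- x %*% sv$v
  got <- as.matrix(pca_samples(em3)$scores[, -1])
  for (j in seq_len(ncol(got))) {
    expect_equal(abs(got[, j]), abs(oracle_scores[, j]),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  # orthogonal scores
  cp <- crossprod(as.matrix(p$scores[, -1]))
  expect_equal(cp[lower.tri(cp)], rep(0, sum(lower.tri(cp))), tolerance = 1e-8)
})
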