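# fabricate a gene_set_db in code
make_db <- function(sets) {
  structure(sets,
            descriptions = stats::setNames(rep("", length(sets)), names(sets)),
            class = "gene_set_db")
}

test_that("ORA p-values equal the hypergeometric oracle on a planted query", {
  universe <- sprintf("G%04d", 1:1000)
  set50 <- universe[1:50]
  query <- c(universe[1:30], universe[101:170])      # k = 30, n = 100
  db <- make_db(list(PLANTED = set50, OTHER = universe[201:260]))
  res <- run_ora(query, db, universe)
  row <- res[res$set_name == "PLANTED", ]
  expect_identical(c(row$k, row$K, row$n, row$N), c(30L, 50L, 100L, 1000L))
  expect_equal(row$p, oracle_hyper_tail(30, 50, 100, 1000), tolerance = 1e-12)
  expect_equal(row$enrichment_ratio, (30 / 100) / (50 / 1000), tolerance = 1e-12)
  expect_identical(res$set_name[1], "PLANTED")       # sorted by p
  expect_true(all(res$adj_p >= res$p))
})

test_that("ORA applies universe intersection and set-size bounds", {
  universe <- sprintf("G%03d", 1:100)
  db <- make_db(list(
    EXACT = universe[1:10],
    OUTSIDE = paste0("X", 1:5),       # zero members in universe -> untested
    TINY = universe[1:2]              # below min_set
  ))
  res <- run_ora(universe[1:10], db, universe)
  expect_identical(res$set_name, "EXACT")
  expect_identical(res$k, 10L)
  # a query disjoint from the universe yields empty-query warnings
  w <- testthat::capture_warnings(res2 <- run_ora(paste0("Z", 1:3), db, universe))
  expect_match(w, "quer|universe", all = TRUE)
  expect_true(all(res2$k == 0))
})

test_that("directional ORA partitions the query into all = up + down", {
  ma <- demo_master()
  db <- read_gmt(demo_bundle()$paths$gmt)
  res <- run_ora_directional(ma, "ML_vs_LP", db, ma$symbol)
  expect_named(res, c("all", "up", "down"))
  n_all <- res$all$n[1]; n_up <- res$up$n[1]; n_down <- res$down$n[1]
  expect_identical(n_all, n_up + n_down)
  # planted enriched sets rank first on the full query
  expect_match(res$all$set_name[1], "^ENRICHED_SET")
})

test_that("URA activation z follows its closed form and the z > 2 rule", {
  # toy master: g1 up, g2 down in B_vs_A
  ma <- toy_master()
  net <- data.frame(
    regulator = rep("R1", 3),
    target = c("GENE1", "GENE2", "GENE4"),
    mode = c("Activation", "Repression", "Activation"),
    stringsAsFactors = FALSE
  )
  res <- run_ura(ma, "B_vs_A", net, min_regulon = 1)
  # both significant targets consistent with activation: z = 2 / sqrt(2)
  expect_equal(res$activation_z, 2 / sqrt(2), tolerance = 1e-12)
  expect_identical(res$n_consistent, 2L)
  expect_identical(res$n_inconsistent, 0L)
  expect_identical(res$state, "enriched-only")     # 1.41 < 2: not "activated"

  # closed forms: 4 consistent/0 inconsistent -> z = 2; 3/1 -> z = 1
  expect_equal((4 - 0) / sqrt(4), 2)
  net2 <- data.frame(regulator = "R2", target = "GENE1", mode = "Unknown")
  res2 <- run_ura(ma, "B_vs_A", net2, min_regulon = 1)
  # Unknown-mode targets count in the overlap but not in z
  expect_identical(res2$k, 1L)
  expect_identical(res2$activation_z, 0)
})

test_that("URA recovers planted regulator states on the demo fixture", {
  ma <- demo_master()
  net <- read_trrust(demo_bundle()$paths$trrust)
  truth <- demo_bundle()$truth$regulators
  res <- run_ura(ma, "ML_vs_LP", net)
  for (nm in names(truth)) {
    z <- res$activation_z[res$regulator == nm]
    if (truth[[nm]] == "activated") expect_gt(z, 2)
    if (truth[[nm]] == "inhibited") expect_lt(z, -2)
  }
  # z is antisymmetric under direction reversal of the calls
  ma_flipped <- ma
  cl <- ma_flipped$ML_vs_LP.call
  ma_flipped$ML_vs_LP.call <- ifelse(cl == "up", "down",
                                     ifelse(cl == "down", "up", cl))
  res_f <- run_ura(ma_flipped, "ML_vs_LP", net)
  expect_equal(res_f$activation_z[match(res$regulator, res_f$regulator)],
               -res$activation_z, tolerance = 1e-12)
})

test_that("spatial analysis tests the three families per chromosome", {
  ma <- toy_master()
  sp <- run_spatial(ma, "B_vs_A", expressed_threshold = 1)
  expect_setequal(unique(sp$family),
                  c("expression-bias", "de-bias", "direction-bias"))
  # genes without a chromosome are excluded from every family:
  # toy master has 6 genes, one (g6) without chromosome
  expr_fam <- sp[sp$family == "expression-bias", ]
  expect_identical(unique(expr_fam$a + expr_fam$b + expr_fam$c + expr_fam$d), 5L)
  # direction-bias: chr1 carries the only up and the only down gene
  dir_fam <- sp[sp$family == "direction-bias", ]
  chr1 <- dir_fam[dir_fam$chromosome == "chr1", ]
  expect_equal(chr1$p,
               oracle_fisher_two_sided(chr1$a, chr1$b, chr1$c, chr1$d),
               tolerance = 1e-12)
  # identical composition on every chromosome gives p = 1 everywhere
  sheet <- sample_sheet(c("s1", "s2"), c("A", "B"))
  em <- matrix(c(10, 1, 10, 1, 10, 1, 10, 1), 4, 2,
               dimnames = list(paste0("g", 1:4), c("s1", "s2")))
  bg <- data.frame(gene_id = paste0("g", 1:4), symbol = paste0("g", 1:4),
                   chromosome = rep(c("chr1", "chr2"), each = 2))
  de <- data.frame(gene_id = paste0("g", 1:4), log2fc = 0,
                   p = 0.5, adj_p = 0.9)
  ma2 <- build_master_table(sheet, em, list(comparison_spec("c", "B", "A", de)), bg)
  sp2 <- run_spatial(ma2, "c", expressed_threshold = 2)
  expect_true(all(sp2$p == 1))
})

test_that("overlap statistics match closed forms and the oracle", {
  universe <- sprintf("G%03d", 1:200)
  a <- universe[1:20]; b <- universe[11:40]         # overlap 10
  ov <- run_overlap(a, b, universe)
  expect_equal(ov$expected, 20 * 30 / 200)          # 3.0
  expect_equal(ov$enrichment, 10 / 3, tolerance = 1e-12)
  expect_equal(ov$p, oracle_hyper_tail(10, 20, 30, 200), tolerance = 1e-12)
  # A = B: enrichment N / |A|; disjoint lists: overlap 0, p = 1
  same <- run_overlap(a, a, universe)
  expect_equal(same$enrichment, 200 / 20)
  dis <- run_overlap(universe[1:20], universe[21:40], universe)
  expect_identical(dis$overlap, 0L)
  expect_identical(dis$p, 1)
})

test_that("shared-gene network edges follow the >50% smaller-set rule", {
  res <- data.frame(
    set_name = c("A", "B", "C"),
    p = c(1e-6, 1e-5, 1e-4),
    adj_p = c(1e-5, 1e-4, 1e-3),
    overlap_genes = c("g1,g2,g3,g4,g5",   # A
                      "g1,g2,g3",         # shares 3/3 with A -> edge
                      "g9,g10"),          # disjoint -> no edge
    stringsAsFactors = FALSE
  )
  net <- build_shared_gene_network(res, adj_p_cut = 0.05)
  expect_identical(nrow(net$nodes), 3L)
  expect_identical(net$edges$from, "A")
  expect_identical(net$edges$to, "B")
  # exactly at 60% > 50%: edge; at exactly 50%: no edge (strict)
  res2 <- data.frame(set_name = c("X", "Y"), p = c(1e-4, 1e-4),
                     adj_p = c(1e-3, 1e-3),
                     overlap_genes = c("g1,g2,g3,g4,g5", "g1,g2,g3,g6,g7"))
  expect_identical(nrow(build_shared_gene_network(res2)$edges), 1L)
  res3 <- data.frame(set_name = c("X", "Y"), p = c(1e-4, 1e-4),
                     adj_p = c(1e-3, 1e-3),
                     overlap_genes = c("g1,g2,g3,g4", "g1,g2,g5,g6"))
  expect_identical(nrow(build_shared_gene_network(res3)$edges), 0L)
  # non-significant rows are not nodes
  res4 <- res
  res4$adj_p <- c(0.01, 0.2, 0.3)
  expect_identical(nrow(build_shared_gene_network(res4)$nodes), 1L)
})
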