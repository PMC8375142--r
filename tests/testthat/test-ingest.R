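write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

test_that("sample sheets preserve first-appearance group order and validate ids", {
  f <- write_lines_tmp(c("sample\tgroup",
                         "LP_1\tLP", "LP_2\tLP", "ML_1\tML",
                         "ML_2\tML", "MLN_1\tMLN", "MLN_2\tMLN"))
  sh <- read_sample_sheet(f)
  expect_identical(sh$group_order, c("LP", "ML", "MLN"))
  expect_identical(sh$samples$sample_id[1], "LP_1")

  f1 <- write_lines_tmp(c("sample\tgroup", "only\tG"))
  sh1 <- read_sample_sheet(f1)
  expect_identical(sh1$group_order, "G")

  fdup <- write_lines_tmp(c("sample\tgroup", "s1\tA", "s1\tB"))
  expect_error(read_sample_sheet(fdup), "s1")
  fempty <- write_lines_tmp("sample\tgroup")
  expect_error(read_sample_sheet(fempty), "empty")
  expect_error(sample_sheet(c("a", "b"), c("A", "B"), group_order = c("A")),
               "permutation")
})

test_that("expression matrices are validated cell-wise with coordinates", {
  f <- write_lines_tmp(c("gene_id\ts1\ts2\ts3",
                         "g1\t1\t2\t3", "g2\t0\t0.5\t1",
                         "g3\t9\t8\t7", "g4\t1\t1\t1"))
  em <- read_expression_matrix(f)
  expect_identical(dim(em), c(4L, 3L))
  expect_identical(rownames(em), paste0("g", 1:4))

  fneg <- write_lines_tmp(c("gene_id\ts1", "g1\t-1"))
  expect_error(read_expression_matrix(fneg), "negative")
  fbad <- write_lines_tmp(c("gene_id\ts1\ts2", "g1\t1\ttwo"))
  expect_error(read_expression_matrix(fbad), "row 1, column 's2'")
  # duplicate ids: first row survives, with a warning
  fdup <- write_lines_tmp(c("gene_id\ts1", "g1\t5", "g1\t7", "g2\t1"))
  expect_warning(em2 <- read_expression_matrix(fdup), "duplicate")
  expect_identical(em2["g1", "s1"], 5)
})

test_that("differential tables map common tool headers and flag bad values", {
  deseq <- write_lines_tmp(c("gene_id\tbaseMean\tlog2FoldChange\tpvalue\tpadj",
                             "g1\t10\t1.5\t0.001\t0.005",
                             "g2\t20\t-0.2\t0.6\tNA"))
  expect_warning(de <- read_differential_table(deseq), "untested")
  expect_identical(names(de), c("gene_id", "log2fc", "p", "adj_p"))
  expect_equal(de$log2fc, c(1.5, -0.2))
  expect_true(is.na(de$adj_p[2]))     # retained as missing, flagged upstream

  edger <- write_lines_tmp(c("gene\tlogFC\tlogCPM\tPValue\tFDR",
                             "g1\t2\t5\t0.01\t0.04"))
  de2 <- read_differential_table(edger)
  expect_equal(de2$adj_p, 0.04)

  bad <- write_lines_tmp(c("gene_id\tlog2fc\tp\tadj_p", "g1\t1\t1.5\t0.2"))
  expect_error(read_differential_table(bad), "out of \\[0, 1\\]")
  nocol <- write_lines_tmp(c("gene_id\tfold\tp\tadj_p", "g1\t1\t0.5\t0.2"))
  expect_error(read_differential_table(nocol), "log2fc")
})

test_that("GMT parsing drops empty sets and de-duplicates members", {
  f <- write_lines_tmp(c("SET_A\tdesc a\tG1\tG2\tG3",
                         "SET_B\tdesc b\tG2\tG2\tG4",
                         "SET_EMPTY\tno members"))
  expect_warning(db <- read_gmt(f), "SET_EMPTY")
  expect_length(db, 2)
  expect_identical(db$SET_B, c("G2", "G4"))
  expect_identical(unname(attr(db, "descriptions")["SET_A"]), "desc a")
})

test_that("regulator networks close the mode vocabulary", {
  f <- write_lines_tmp(c("TP53\tMDM2\tActivation\t123",
                         "TP53\tCDKN1A\tRepression\t9",
                         "MYC\tX1\tweird\t1",
                         "TP53\tMDM2\tRepression\t4"))  # duplicate pair
  expect_warning(net <- read_trrust(f), "Unknown")
  expect_identical(nrow(net), 3L)
  expect_identical(net$mode[net$regulator == "MYC"], "Unknown")
  expect_identical(net$mode[net$target == "MDM2"], "Activation")  # first kept
})

test_that("master-table calls honour thresholds and partition the genes", {
  # thresholds (0.01, 1): adj_p = 0.005 with lfc 1.5 -> up; lfc -0.5 -> ns
  sheet <- sample_sheet(c("a1", "a2", "b1", "b2"), rep(c("A", "B"), each = 2))
  em <- matrix(c(1, 2, 3, 4), 3, 4, byrow = TRUE,
               dimnames = list(c("g1", "g2", "g3"), c("a1", "a2", "b1", "b2")))
  em[2, ] <- c(5, 6, 7, 8); em[3, ] <- 2
  de <- data.frame(gene_id = c("g1", "g2"),
                   log2fc = c(1.5, -0.5), p = c(0.001, 0.001),
                   adj_p = c(0.005, 0.005))
  ma <- build_master_table(sheet, em, list(
    comparison_spec("c", "B", "A", de, adj_p_threshold = 0.01,
                    abs_log2fc_threshold = 1)))
  calls <- master_calls(ma, "c")
  expect_identical(unname(calls), c("up", "ns", "untested"))
  # partition: up + down + ns + untested = all genes
  expect_identical(sum(table(calls)), 3L)
  # constant gene gets an all-zero z row
  expect_identical(unname(master_z(ma)["g3", ]), rep(0, 4))
})

test_that("per-gene z-scores are standardized across samples", {
  ma <- toy_master()
  z <- master_z(ma)
  nonconst <- apply(master_expr(ma), 1, stats::sd) > 0
  expect_lt(max(abs(rowMeans(z[nonconst, ]))), 1e-9)
  expect_lt(max(abs(apply(z[nonconst, ], 1, stats::sd) - 1)), 1e-9)
})

test_that("toy master-table calls and untested handling are as designed", {
  ma <- toy_master()
  calls <- master_calls(ma, "B_vs_A")
  expect_identical(unname(calls[c("g1", "g2", "g6")]),
                   c("up", "down", "untested"))
  counts <- table(factor(calls, c("up", "down", "ns", "untested")))
  expect_identical(sum(counts), nrow(ma))
})

test_that("the master table round-trips through TSV exactly", {
  ma <- toy_master()
  f <- tempfile(fileext = ".tsv")
  write_master_table(ma, f)
  back <- read_master_table(f)
  expect_identical(names(ma), names(back))
  expect_identical(as.list(ma), as.list(back))  # bitwise-equal columns
  expect_identical(master_samples(ma), master_samples(back))
  expect_identical(master_comparisons(ma)$B_vs_A$adj_p_threshold,
                   master_comparisons(back)$B_vs_A$adj_p_threshold)
})

test_that("a DE table sharing no genes with the EM is an error", {
  sheet <- sample_sheet(c("s1", "s2"), c("A", "B"))
  em <- matrix(1:4, 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  de <- data.frame(gene_id = "other", log2fc = 1, p = 0.5, adj_p = 0.5)
  expect_error(
    build_master_table(sheet, em, list(comparison_spec("c", "B", "A", de))),
    "no genes shared")
})
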