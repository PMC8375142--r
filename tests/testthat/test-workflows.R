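test_that("the registry is pinned to the published per-category counts", {
  counts <- registry_counts()
  expect_identical(counts[["qc"]], 1L)
  expect_identical(counts[["expression"]], 7L)
  expect_identical(counts[["differential"]], 33L)
  expect_identical(counts[["multiple"]], 9L)
  expect_identical(counts[["total"]], 50L)
  reg <- plot_registry()
  expect_identical(anyDuplicated(reg$type_id), 0L)
})

test_that("a demo-shaped run produces every artifact with its three files", {
  run <- demo_run()
  arts <- run$result$artifacts
  expect_gt(length(arts), 50)
  for (a in arts) {
    inst_dir <- file.path(run$out, a$instance)
    expect_true(file.exists(file.path(inst_dir, a$data_file)))
    expect_true(file.exists(file.path(inst_dir, a$script_file)))
    for (img in a$images) expect_true(file.exists(file.path(inst_dir, img)))
  }
  # manifest mirrors the artifact list
  expect_identical(length(run$manifest$artifacts$id), length(arts))
  expect_setequal(run$manifest$artifacts$id,
                  vapply(arts, `[[`, character(1), "id"))
})

test_that("the run emits the full plot-type registry per category", {
  run <- demo_run()
  counts <- unlist(run$manifest$plot_type_counts)
  expect_identical(counts[["qc"]], 1L)
  expect_identical(counts[["expression"]], 7L)
  expect_identical(counts[["differential"]], 33L)
  expect_identical(counts[["multiple"]], 9L)
  expect_identical(counts[["total"]], 50L)
})

test_that("plot data files agree with the master-table statistics", {
  run <- demo_run()
  master <- run$result$master
  # density data has one row per gene per sample
  dens <- read_tsv_test(run$out, "ne1", "ne1_ne_density.tsv")
  expect_identical(nrow(dens), nrow(master) * length(master_samples(master)))
  # up/down bar totals equal master-table call counts
  bar <- read_tsv_test(run$out, "de1", "de1_de_counts_bar.tsv")
  calls <- master_calls(master, "ML_vs_LP")
  expect_identical(bar$value[bar$category == "up"], sum(calls == "up"))
  expect_identical(bar$value[bar$category == "down"], sum(calls == "down"))
  # volcano rows carry only the significant/non-significant colours
  vol <- read_tsv_test(run$out, "de1", "de1_de_volcano.tsv")
  expect_setequal(unique(vol$colour), c("significant", "not significant"))
  expect_identical(sum(vol$colour == "significant"), sum(calls %in% c("up", "down")))
  # top-expressed table: top_n rows per group ordered by that group's mean
  top <- read_tsv_test(run$out, "ne1", "ne1_ne_top_genes_table.tsv")
  expect_identical(nrow(top), 5L * length(master_group_order(master)))
  for (g in master_group_order(master)) {
    got <- top$symbol[top$group == g]
    want <- master$symbol[order(-master[[paste0("mean.", g)]], master$symbol)][1:5]
    expect_identical(got, want)
  }
  # fold-vs-fold categories partition the genes tested in both comparisons
  ff <- read_tsv_test(run$out, "mde1", "mde1_mde_fold_fold_ML_vs_LP_MLN_vs_ML.tsv")
  both_tested <- sum(!is.na(master$ML_vs_LP.log2fc) & !is.na(master$MLN_vs_ML.log2fc))
  expect_identical(nrow(ff), both_tested)
  expect_true(all(ff$colour %in% c("both", "first only", "second only", "neither")))
  # union heatmap covers exactly the union of significant genes
  hm <- read_tsv_test(run$out, "mde1", "mde1_mde_union_heatmap_clustered.tsv")
  calls2 <- master_calls(master, "MLN_vs_ML")
  union_n <- sum(calls %in% c("up", "down") | calls2 %in% c("up", "down"))
  expect_identical(length(unique(hm$row)), union_n)
})

test_that("signature artifacts expose the meta-gene per sample", {
  run <- demo_run()
  mg <- read_tsv_test(run$out, "mde1", "mde1_mde_signature_violin_1.tsv")
  master <- run$result$master
  # one value per sample, grouped by sample group
  expect_identical(nrow(mg), length(master_samples(master)))
  assignments <- read_tsv_test(run$out, "mde1", "mde1_signatures.tsv")
  sig1 <- assignments$gene_id[assignments$signature == 1]
  expect_equal(sort(unique(mg$y)),
               sort(unique(unname(compute_metagene(sig1, master)))),
               tolerance = 1e-12)
})

test_that("reports are self-contained, complete and internally linked", {
  testthat::skip_if_not_installed("xml2")
  run <- demo_run()
  for (inst in names(run$result$instances)) {
    html <- xml2::read_html(file.path(run$out, inst, "report.html"))
    arts <- Filter(function(a) a$instance == inst, run$result$artifacts)
    # every artifact appears exactly once, with its anchor resolvable
    hrefs <- xml2::xml_attr(xml2::xml_find_all(html, "//div[@id='sidebar']//a"), "href")
    ids <- xml2::xml_attr(xml2::xml_find_all(html, "//div[@class='artifact']"), "id")
    expect_identical(sort(ids), sort(vapply(arts, `[[`, character(1), "id")))
    expect_setequal(sub("^#", "", hrefs), ids)
    # images are embedded (self-contained), and drop-downs are present
    imgs <- xml2::xml_attr(xml2::xml_find_all(html, "//img"), "src")
    expect_true(all(grepl("^data:image/png;base64", imgs)))
    expect_gte(length(xml2::xml_find_all(html, "//details")), length(arts))
  }
  expect_true(file.exists(file.path(run$out, "index.html")))
})

test_that("each per-plot script re-executes standalone from its data file", {
  run <- demo_run()
  # spot-check one artifact per family, deleting the image first
  arts <- run$result$artifacts
  fams <- plot_registry()$family[match(vapply(arts, `[[`, character(1), "type_id"),
                                       plot_registry()$type_id)]
  picks <- arts[!duplicated(fams)]
  for (a in picks) {
    inst_dir <- file.path(run$out, a$instance)
    img <- file.path(inst_dir, a$images[1])
    unlink(img)
    rnaevi:::run_plot_script(file.path(inst_dir, a$script_file))
    expect_true(file.exists(img))
  }
  # and one genuinely standalone re-execution through Rscript
  a <- picks[[1]]
  inst_dir <- file.path(run$out, a$instance)
  img <- file.path(inst_dir, a$images[1])
  unlink(img)
  status <- withr::with_dir(file.path(inst_dir, "scripts"),
                            system2("Rscript", basename(a$script_file),
                                    stdout = FALSE, stderr = FALSE))
  expect_identical(status, 0L)
  expect_true(file.exists(img))
})

test_that("validation failures are consolidated into one error before analysis", {
  cfg <- run_config(sample_sheet = "missing1.tsv", em = "missing2.tsv",
                    workflows = list(list(kind = "DE", comparison = "nope")))
  err <- tryCatch(run_pipeline(cfg, tempfile()), error = function(e) e)
  msg <- conditionMessage(err)
  expect_match(msg, "missing1.tsv")
  expect_match(msg, "missing2.tsv")
  expect_match(msg, "nope")
})

test_that("a run with zero significant genes still completes with empty states", {
  cfg <- fixture_config(groups = c("A", "B"), reps_per_group = 3,
                        n_genes = 60, profiles = list(), seed = 5)
  d <- file.path(tempdir(), "nullrun-in"); unlink(d, recursive = TRUE)
  res <- generate_experiment(cfg, d)
  out <- file.path(tempdir(), "nullrun-out"); unlink(out, recursive = TRUE)
  rc <- run_config(
    sample_sheet = res$paths$sample_sheet, em = res$paths$em,
    background = res$paths$background, de_tables = as.list(res$paths$de),
    comparisons = list(list(name = "B_vs_A", test = "B", ref = "A",
                            de = "B_vs_A", adj_p_threshold = 1e-6)),
    workflows = list(list(kind = "DE", comparison = "B_vs_A")),
    formats = "png", dpi = 96, seed = 3)
  r <- run_pipeline(rc, out)
  expect_length(r$artifacts, 33)
  expect_true(file.exists(file.path(out, "de1", "report.html")))
})
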