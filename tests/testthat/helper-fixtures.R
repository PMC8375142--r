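# Shared test fixtures. Expensive artefacts (the demo bundle and a full
# pipeline run over it) are built once per test session and cached.

.cache <- new.env(parent = emptyenv())

digest_file <- function(path) unname(tools::md5sum(path))

read_tsv_test <- function(out, inst, file) {
  utils::read.delim(file.path(out, inst, "data", file), sep = "\t",
                    header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

cached <- function(key, builder) {
  if (!exists(key, envir = .cache)) assign(key, builder(), envir = .cache)
  get(key, envir = .cache)
}

# minimal hand-built master table: 6 genes x 2 groups x 3 reps, one comparison
toy_master <- function(adj_p_threshold = 0.05, abs_log2fc_threshold = 1) {
  sheet <- sample_sheet(paste0("s", 1:6), rep(c("A", "B"), each = 3))
  em <- rbind(
    g1 = c(1, 2, 3, 10, 11, 12),   # clearly up in B
    g2 = c(10, 11, 12, 1, 2, 3),   # clearly down in B
    g3 = c(5, 5, 5, 5, 5, 5),      # constant
    g4 = c(3, 4, 5, 4, 5, 6),      # unremarkable
    g5 = c(2, 3, 4, 3, 2, 4),      # unremarkable
    g6 = c(8, 9, 7, 9, 8, 10)      # unremarkable
  )
  colnames(em) <- paste0("s", 1:6)
  de <- data.frame(
    gene_id = paste0("g", 1:5),     # g6 absent -> untested
    log2fc = c(2.5, -2.5, 0, 0.4, -0.2),
    p = c(1e-4, 2e-4, 0.9, 0.4, 0.6),
    adj_p = c(5e-4, 8e-4, 0.95, 0.6, 0.7),
    stringsAsFactors = FALSE
  )
  bg <- data.frame(gene_id = paste0("g", 1:6),
                   symbol = paste0("GENE", 1:6),
                   chromosome = c("chr1", "chr1", "chr2", "chr2", "chr3", ""),
                   biotype = "protein_coding", stringsAsFactors = FALSE)
  build_master_table(
    sheet, em,
    list(comparison_spec("B_vs_A", "B", "A", de, adj_p_threshold,
                         abs_log2fc_threshold)),
    bg
  )
}

demo_bundle <- function() {
  cached("demo_bundle", function() {
    dir <- file.path(tempdir(), "rnaevi-demo-bundle")
    unlink(dir, recursive = TRUE)
    generate_minimal_demo(dir, seed = 101)
  })
}

demo_run_config <- function(paths, seed = 7, ...) {
  run_config(
    sample_sheet = paths$sample_sheet, em = paths$em,
    background = paths$background, de_tables = as.list(paths$de),
    comparisons = list(
      list(name = "ML_vs_LP", test = "ML", ref = "LP", de = "ML_vs_LP"),
      list(name = "MLN_vs_ML", test = "MLN", ref = "ML", de = "MLN_vs_ML")
    ),
    workflows = list(
      list(kind = "NE"),
      list(kind = "DE", comparison = "ML_vs_LP"),
      list(kind = "DE", comparison = "MLN_vs_ML"),
      list(kind = "MDE", comparisons = c("ML_vs_LP", "MLN_vs_ML"))
    ),
    gmt = paths$gmt, trrust = paths$trrust, seed = seed, ...
  )
}

# one full default demo run per session (also records its peak memory and
# wall time, used by the resource-contract checks)
demo_run <- function() {
  cached("demo_run", function() {
    bundle <- demo_bundle()
    out <- file.path(tempdir(), "rnaevi-demo-run")
    unlink(out, recursive = TRUE)
    invisible(gc(reset = TRUE, full = TRUE))
    t0 <- proc.time()[["elapsed"]]
    res <- run_pipeline(demo_run_config(bundle$paths), out)
    elapsed <- proc.time()[["elapsed"]] - t0
    g <- gc()
    peak_mb <- sum(g[, "max used"] * c(56, 8)) / 2^20
    list(out = out, result = res, elapsed = elapsed, peak_mb = peak_mb,
         manifest = jsonlite::read_json(res$manifest_path,
                                        simplifyVector = TRUE))
  })
}

# master table built straight from the demo bundle files
demo_master <- function() {
  cached("demo_master", function() {
    bundle <- demo_bundle()
    sheet <- read_sample_sheet(bundle$paths$sample_sheet)
    em <- read_expression_matrix(bundle$paths$em)
    bg <- read_background(bundle$paths$background)
    cmps <- lapply(names(bundle$paths$de), function(nm) {
      parts <- strsplit(nm, "_vs_")[[1]]
      comparison_spec(nm, parts[1], parts[2],
                      read_differential_table(bundle$paths$de[[nm]]))
    })
    build_master_table(sheet, em, cmps, bg)
  })
}

# strong-effect fixture for recovery checks: 3 groups x 10 reps, 180 genes,
# 4 planted profiles of 40 genes; |log2fc| 4 at the default noise sd, with
# stringent call thresholds (see the methods vignette for the power analysis:
# a missed call in one comparison creates a spurious partial-profile bin, so
# exact-count recovery needs per-gene, per-comparison power near 1 and an
# expected null false-positive count near 0)
recovery_config <- function(seed) {
  fixture_config(
    groups = c("A", "B", "C"), reps_per_group = 10, n_genes = 180,
    profiles = list(
      list(profile = c("up", "up"), n = 40),
      list(profile = c("up", "down"), n = 40),
      list(profile = c("down", "up"), n = 40),
      list(profile = c("down", "down"), n = 40)
    ),
    lfc_default = 4, seed = seed
  )
}

recovery_master <- function(seed, adj_p_threshold = 1e-4) {
  dir <- file.path(tempdir(), sprintf("rnaevi-recovery-%d", seed))
  unlink(dir, recursive = TRUE)
  res <- generate_experiment(recovery_config(seed), dir)
  sheet <- read_sample_sheet(res$paths$sample_sheet)
  em <- read_expression_matrix(res$paths$em)
  cmps <- lapply(names(res$paths$de), function(nm) {
    parts <- strsplit(nm, "_vs_")[[1]]
    comparison_spec(nm, parts[1], parts[2],
                    read_differential_table(res$paths$de[[nm]]),
                    adj_p_threshold = adj_p_threshold)
  })
  master <- build_master_table(sheet, em, cmps)
  unlink(dir, recursive = TRUE)
  list(master = master, truth = res$truth)
}
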