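# Synthetic input bundles with planted, machine-readable ground truth.
#
# Model: per-gene baseline log10 expression ~ Normal(base_mean, base_sd);
# planted genes receive per-group shifts implied by their call profile
# (log2 fold changes converted to log10); per-sample Gaussian noise on the
# log10 scale. The emitted DE tables are then *computed* from the generated
# expression matrix (per-gene Welch t-test on log10 values, BH adjusted), so
# expression and differential files can never contradict each other.

#' Fixture configuration
#'
#' Describes one synthetic experiment. Comparisons are consecutive group
#' pairs: comparison i tests group i+1 against group i, so a profile vector
#' of length m requires m+1 groups.
#'
#' @param groups Character vector of group labels (>= 2).
#' @param reps_per_group Replicates per group (default 3).
#' @param n_genes Total genes (default 1000).
#' @param profiles List of planted profiles, each a list with `profile`
#'   (character vector over comparisons, entries "up"/"down"/"ns"), `n`
#'   (gene count) and optional `lfc` (absolute log2 fold change per step;
#'   default `lfc_default`).
#' @param lfc_default Default planted |log2 fold change| (default 2).
#' @param noise_sd Per-sample noise sd on the log10 scale (default 0.25).
#' @param base_mean,base_sd Baseline log10 expression distribution
#'   (defaults 1.5 and 1).
#' @param gene_sets NULL or list(`n_enriched`, `n_null`, `set_size`,
#'   `overlap_frac`): enriched sets draw `overlap_frac` of their members
#'   from the planted significant genes of comparison 1.
#' @param regulators NULL or list(`n_activated`, `n_inhibited`, `n_null`,
#'   `regulon_size`, `consistency`): activated regulators target planted
#'   comparison-1 up-genes via Activation edges (and down-genes via
#'   Repression); `consistency` is the fraction of signal edges.
#' @param n_chromosomes Chromosomes assigned round-robin (default 10).
#' @param chrom_bias NULL or list(`chromosome`, `fraction`): place that
#'   fraction of comparison-1 up-planted genes on one chromosome.
#' @param seed Mandatory integer seed.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(groups = c("A", "B", "C"),
                           reps_per_group = 3,
                           n_genes = 1000,
                           profiles = list(),
                           lfc_default = 2,
                           noise_sd = 0.25,
                           base_mean = 1.5,
                           base_sd = 1,
                           gene_sets = NULL,
                           regulators = NULL,
                           n_chromosomes = 10,
                           chrom_bias = NULL,
                           seed) {
  if (missing(seed)) evi_abort("fixture seed is mandatory")
  if (length(groups) < 2) evi_abort("need >= 2 groups")
  m <- length(groups) - 1
  planted <- 0L
  for (pr in profiles) {
    if (length(pr$profile) != m) {
      evi_abort("profile length %d != %d comparisons", length(pr$profile), m)
    }
    if (!all(pr$profile %in% c("up", "down", "ns"))) {
      evi_abort("profile entries must be up/down/ns")
    }
    if (all(pr$profile == "ns")) evi_abort("all-ns profiles cannot be planted")
    planted <- planted + pr$n
  }
  if (planted > n_genes) evi_abort("planted gene count %d exceeds n_genes %d",
                                   planted, n_genes)
  structure(
    list(groups = groups, reps_per_group = reps_per_group, n_genes = n_genes,
         profiles = profiles, lfc_default = lfc_default, noise_sd = noise_sd,
         base_mean = base_mean, base_sd = base_sd, gene_sets = gene_sets,
         regulators = regulators, n_chromosomes = n_chromosomes,
         chrom_bias = chrom_bias, seed = as.integer(seed)),
    class = "fixture_config"
  )
}

#' Generate a synthetic experiment bundle
#'
#' Writes a sample sheet, expression matrix, one DE table per comparison, a
#' background annotation file, a GMT gene-set database, a TRRUST-format
#' regulator network and a JSON truth manifest into `dir`. All output is
#' deterministic given the config seed.
#'
#' @param cfg A [fixture_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with file `paths` and the `truth` manifest.
#' @export
generate_experiment <- function(cfg, dir) {
  stopifnot(inherits(cfg, "fixture_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)

  groups <- cfg$groups
  m <- length(groups) - 1
  comparisons <- paste0(groups[-1], "_vs_", groups[-length(groups)])
  reps <- cfg$reps_per_group
  samples <- paste0(rep(groups, each = reps), "_", rep(seq_len(reps), length(groups)))
  sample_group <- rep(groups, each = reps)

  n <- cfg$n_genes
  gene_ids <- sprintf("gene%05d", seq_len(n))
  symbols <- sprintf("SYN%05d", seq_len(n))

  # planted assignment: first genes carry the profiles, remainder are null
  profile_of <- rep(NA_integer_, n)
  true_call <- matrix("ns", n, m, dimnames = list(gene_ids, comparisons))
  true_lfc <- matrix(0, n, m)
  at <- 1L
  for (pi in seq_along(cfg$profiles)) {
    pr <- cfg$profiles[[pi]]
    idx <- seq(at, at + pr$n - 1)
    profile_of[idx] <- pi
    lfc <- pr$lfc %||% cfg$lfc_default
    for (ci in seq_len(m)) {
      true_call[idx, ci] <- pr$profile[ci]
      true_lfc[idx, ci] <- switch(pr$profile[ci], up = lfc, down = -lfc, ns = 0)
    }
    at <- at + pr$n
  }

  # group shifts on the log10 scale, accumulated along the group chain
  shift <- matrix(0, n, length(groups))
  for (ci in seq_len(m)) {
    shift[, ci + 1] <- shift[, ci] + true_lfc[, ci] * log10(2)
  }

  base <- stats::rnorm(n, cfg$base_mean, cfg$base_sd)
  log_expr <- base + shift[, match(sample_group, groups)] +
    matrix(stats::rnorm(n * length(samples), 0, cfg$noise_sd), n)
  em <- 10^log_expr
  dimnames(em) <- list(gene_ids, samples)

  # DE tables from the generated EM: per-gene Welch t on log10 values
  de_tables <- list()
  for (ci in seq_len(m)) {
    test_cols <- sample_group == groups[ci + 1]
    ref_cols <- sample_group == groups[ci]
    xt <- log_expr[, test_cols, drop = FALSE]
    xr <- log_expr[, ref_cols, drop = FALSE]
    mt <- rowMeans(xt); mr <- rowMeans(xr)
    vt <- apply(xt, 1, stats::var); vr <- apply(xr, 1, stats::var)
    nt <- ncol(xt); nr <- ncol(xr)
    se2 <- vt / nt + vr / nr
    tstat <- (mt - mr) / sqrt(se2)
    df <- se2^2 / ((vt / nt)^2 / (nt - 1) + (vr / nr)^2 / (nr - 1))
    p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
    de_tables[[comparisons[ci]]] <- data.frame(
      gene_id = gene_ids,
      log2fc = (mt - mr) / log10(2),
      p = p,
      adj_p = bh_adjust(p),
      stringsAsFactors = FALSE
    )
  }

  # background: chromosomes round-robin, optionally biased for comparison 1
  chromosomes <- paste0("chr", ((seq_len(n) - 1) %% cfg$n_chromosomes) + 1)
  if (!is.null(cfg$chrom_bias)) {
    up1 <- which(true_call[, 1] == "up")
    k <- floor(length(up1) * cfg$chrom_bias$fraction)
    chromosomes[up1[seq_len(k)]] <- cfg$chrom_bias$chromosome
  }
  background <- data.frame(gene_id = gene_ids, symbol = symbols,
                           chromosome = chromosomes,
                           biotype = "protein_coding", stringsAsFactors = FALSE)

  # gene sets: enriched sets sample from planted comparison-1 significant
  # genes; null sets sample uniformly
  sig1 <- symbols[true_call[, 1] %in% c("up", "down")]
  nonsig1 <- setdiff(symbols, sig1)
  gmt_lines <- character()
  set_truth <- list()
  gs <- cfg$gene_sets
  if (!is.null(gs)) {
    for (i in seq_len(gs$n_enriched)) {
      n_sig <- min(round(gs$set_size * gs$overlap_frac), length(sig1))
      members <- c(sample(sig1, n_sig),
                   sample(nonsig1, gs$set_size - n_sig))
      nm <- sprintf("ENRICHED_SET_%02d", i)
      gmt_lines <- c(gmt_lines, paste(c(nm, "synthetic enriched set", members),
                                      collapse = "\t"))
      set_truth[[nm]] <- TRUE
    }
    for (i in seq_len(gs$n_null)) {
      members <- sample(symbols, gs$set_size)
      nm <- sprintf("NULL_SET_%02d", i)
      gmt_lines <- c(gmt_lines, paste(c(nm, "synthetic null set", members),
                                      collapse = "\t"))
      set_truth[[nm]] <- FALSE
    }
  }

  # regulator network: activated regulators point Activation edges at
  # planted comparison-1 up genes (Repression at down genes)
  up1_sym <- symbols[true_call[, 1] == "up"]
  down1_sym <- symbols[true_call[, 1] == "down"]
  trrust_rows <- character()
  reg_truth <- list()
  rg <- cfg$regulators
  if (!is.null(rg)) {
    # `consistency` = fraction of a planted regulon's edges whose mode agrees
    # with the regulator's true state; the remainder are planted inconsistent
    make_reg <- function(nm, signal_up, signal_down, state) {
      size <- rg$regulon_size
      n_cons <- round(size * rg$consistency)
      n_incons <- size - n_cons
      cu <- min(ceiling(n_cons / 2), length(signal_up))
      cd <- min(n_cons - cu, length(signal_down))
      cons_up <- sample(signal_up, cu)        # Activation -> gene moving "up"
      cons_down <- sample(signal_down, cd)    # Repression -> gene moving "down"
      iu <- min(n_incons, length(setdiff(signal_down, cons_down)))
      incons <- sample(setdiff(signal_down, cons_down), iu)  # Activation -> "down"
      rest <- if (size - cu - cd - iu > 0)
        sample(nonsig1, size - cu - cd - iu) else character()
      rows <- c(
        paste(nm, cons_up, "Activation", "1", sep = "\t"),
        paste(nm, cons_down, "Repression", "1", sep = "\t"),
        if (iu > 0) paste(nm, incons, "Activation", "1", sep = "\t"),
        if (length(rest)) paste(nm, rest,
                                sample(c("Activation", "Repression"),
                                       length(rest), replace = TRUE),
                                "1", sep = "\t")
      )
      reg_truth[[nm]] <<- state
      rows
    }
    for (i in seq_len(rg$n_activated)) {
      trrust_rows <- c(trrust_rows, make_reg(sprintf("ACTREG%02d", i),
                                             up1_sym, down1_sym, "activated"))
    }
    for (i in seq_len(rg$n_inhibited)) {
      # inhibited: Activation edges at down genes, Repression at up genes
      trrust_rows <- c(trrust_rows, make_reg(sprintf("INHREG%02d", i),
                                             down1_sym, up1_sym, "inhibited"))
    }
    for (i in seq_len(rg$n_null)) {
      nm <- sprintf("NULLREG%02d", i)
      targets <- sample(symbols, rg$regulon_size)
      trrust_rows <- c(trrust_rows,
                       paste(nm, targets,
                             sample(c("Activation", "Repression"),
                                    length(targets), replace = TRUE),
                             "1", sep = "\t"))
      reg_truth[[nm]] <- "null"
    }
  }

  # write the bundle
  paths <- list(
    sample_sheet = file.path(dir, "sample_sheet.tsv"),
    em = file.path(dir, "expression_matrix.tsv"),
    background = file.path(dir, "background.tsv"),
    gmt = if (length(gmt_lines)) file.path(dir, "gene_sets.gmt") else NULL,
    trrust = if (length(trrust_rows)) file.path(dir, "regulators.tsv") else NULL,
    truth = file.path(dir, "truth_manifest.json")
  )
  utils::write.table(data.frame(sample = samples, group = sample_group),
                     paths$sample_sheet, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  em_df <- data.frame(gene_id = gene_ids,
                      matrix(sprintf("%.17g", em), n,
                             dimnames = list(NULL, samples)),
                      check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(em_df, paths$em, sep = "\t", quote = FALSE, row.names = FALSE)
  paths$de <- character()
  for (ci in seq_len(m)) {
    p <- file.path(dir, paste0("de_", comparisons[ci], ".tsv"))
    write_tsv_exact(de_tables[[ci]], p)
    paths$de[comparisons[ci]] <- p
  }
  utils::write.table(background, paths$background, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(paths$gmt)) writeLines(gmt_lines, paths$gmt)
  if (!is.null(paths$trrust)) writeLines(trrust_rows, paths$trrust)

  truth <- list(
    comparisons = comparisons,
    groups = groups,
    genes = data.frame(gene_id = gene_ids, symbol = symbols,
                       signature = profile_of, true_call,
                       check.names = FALSE, stringsAsFactors = FALSE),
    gene_sets = set_truth,
    regulators = reg_truth,
    config = cfg[setdiff(names(cfg), c("profiles"))],
    profiles = lapply(cfg$profiles, function(pr) {
      list(profile = pr$profile, n = pr$n, lfc = pr$lfc %||% cfg$lfc_default)
    })
  )
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(list(paths = paths, truth = truth,
                 em = em, de_tables = de_tables))
}

#' Generate the bundled demonstration experiment
#'
#' Three groups (LP, ML, MLN) with three replicates each, two consecutive
#' comparisons, four planted call profiles of 40 genes each, five enriched
#' plus 25 null gene-sets and a small regulator network. The planted effect
#' (|log2fc| = 4, noise sd 0.15) is deliberately strong so that with n = 3
#' per group the planted structure is recoverable by the two-group test.
#'
#' @param dir Output directory.
#' @param seed Integer seed (default 101).
#' @return Invisibly, the [generate_experiment()] result.
#' @export
generate_minimal_demo <- function(dir, seed = 101) {
  cfg <- fixture_config(
    groups = c("LP", "ML", "MLN"),
    reps_per_group = 3,
    n_genes = 1200,
    profiles = list(
      list(profile = c("up", "up"), n = 40),
      list(profile = c("up", "down"), n = 40),
      list(profile = c("down", "ns"), n = 40),
      list(profile = c("down", "down"), n = 40)
    ),
    lfc_default = 4,
    noise_sd = 0.15,
    gene_sets = list(n_enriched = 5, n_null = 25, set_size = 40,
                     overlap_frac = 0.75),
    regulators = list(n_activated = 3, n_inhibited = 2, n_null = 5,
                      regulon_size = 15, consistency = 0.9),
    seed = seed
  )
  generate_experiment(cfg, dir)
}
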