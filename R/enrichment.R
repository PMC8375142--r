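# Pathway-level analyses: over-representation (ORA), upstream-regulator
# analysis (URA), per-chromosome (spatial) enrichment, pairwise list overlap,
# and the shared-genes network.
#
# Universe convention: the genes measured in the EM that carry a symbol in
# the background file, matched to databases case-insensitively by symbol.

#' Over-representation analysis
#'
#' Hypergeometric enrichment of a query gene list in each set of a GMT
#' database, with BH correction across all tested sets. Sets are intersected
#' with the universe first; only sets with `min_set <= K <= max_set` members
#' in the universe are tested.
#'
#' @param query Character vector of gene symbols (intersected with the
#'   universe; matching is case-insensitive).
#' @param db A `gene_set_db` from [read_gmt()].
#' @param universe Character vector of background gene symbols.
#' @param min_set,max_set Set-size bounds after universe intersection
#'   (defaults 3 and 2000).
#' @return data.frame sorted by p: `set_name`, `description`, `k`, `K`, `n`,
#'   `N`, `enrichment_ratio`, `p`, `adj_p`, `overlap_genes` (comma-joined).
#' @export
run_ora <- function(query, db, universe, min_set = 3, max_set = 2000) {
  if (!length(db)) evi_abort("empty gene-set database")
  universe <- unique(canon_symbol(universe))
  query0 <- unique(canon_symbol(query))
  query <- intersect(query0, universe)
  if (length(query) < length(query0)) {
    evi_warn("%d query gene(s) not in the universe were dropped",
             length(query0) - length(query))
  }
  if (!length(query)) evi_warn("empty query after universe intersection")
  N <- length(universe)
  n <- length(query)
  desc <- attr(db, "descriptions")
  rows <- lapply(names(db), function(nm) {
    members <- intersect(unique(canon_symbol(db[[nm]])), universe)
    K <- length(members)
    if (K < min_set || K > max_set) return(NULL)
    hit <- intersect(members, query)
    k <- length(hit)
    data.frame(
      set_name = nm,
      description = unname(desc[nm] %||% ""),
      k = k, K = K, n = n, N = N,
      enrichment_ratio = if (n > 0) (k / n) / (K / N) else 0,
      p = if (n > 0) hypergeometric_tail(k, K, n, N) else 1,
      overlap_genes = paste(sort(hit), collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(set_name = character(), description = character(),
                      k = integer(), K = integer(), n = integer(), N = integer(),
                      enrichment_ratio = numeric(), p = numeric(),
                      adj_p = numeric(), overlap_genes = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p)
  out <- out[order(out$p, out$set_name), ]
  out <- out[c("set_name", "description", "k", "K", "n", "N",
               "enrichment_ratio", "p", "adj_p", "overlap_genes")]
  rownames(out) <- NULL
  out
}

#' Directional over-representation analysis
#'
#' Runs [run_ora()] three times for one comparison: all significant genes,
#' upregulated only, and downregulated only.
#'
#' @param master A master gene table.
#' @param comparison Comparison name (as used in [comparison_spec()]).
#' @param db A `gene_set_db`.
#' @param universe Background symbols; defaults to all master-table symbols.
#' @param ... Passed to [run_ora()].
#' @return Named list of three result data.frames: `all`, `up`, `down`.
#' @export
run_ora_directional <- function(master, comparison, db, universe = NULL, ...) {
  universe <- universe %||% master$symbol
  lapply(
    stats::setNames(c("all", "up", "down"), c("all", "up", "down")),
    function(d) {
      suppressWarnings(
        run_ora(significant_symbols(master, comparison, d), db, universe, ...)
      )
    }
  )
}

#' Upstream regulator analysis
#'
#' For each regulator in a signed regulator -> target network, tests whether
#' its regulon is over-represented among the significant genes of a
#' comparison (hypergeometric, BH across regulators) and computes the
#' activation z-score from the signed agreement between edge mode and gene
#' direction: a significant target is consistent with activation if
#' (Activation and up) or (Repression and down), inconsistent if the
#' opposite; Unknown-mode targets count in the overlap but not in z.
#' z = (consistent - inconsistent) / sqrt(consistent + inconsistent).
#' State: `activated` if z > 2, `inhibited` if z < -2, else `enriched-only`.
#'
#' @param master A master gene table.
#' @param comparison Comparison name.
#' @param net data.frame from [read_trrust()].
#' @param universe Background symbols; defaults to all master-table symbols.
#' @param min_regulon Minimum regulon size in the universe (default 3).
#' @return data.frame sorted by p: `regulator`, `K` (regulon size), `k`
#'   (significant targets), `n`, `N`, `n_consistent`, `n_inconsistent`,
#'   `n_unknown`, `activation_z`, `p`, `adj_p`, `state`, `overlap_genes`.
#' @export
run_ura <- function(master, comparison, net, universe = NULL, min_regulon = 3) {
  universe <- unique(canon_symbol(universe %||% master$symbol))
  N <- length(universe)
  calls <- master_calls(master, comparison)
  sym <- canon_symbol(master$symbol)
  up <- unique(sym[calls == "up"])
  down <- unique(sym[calls == "down"])
  sig <- union(up, down)
  sig <- intersect(sig, universe)
  n <- length(sig)

  net$target_c <- canon_symbol(net$target)
  rows <- lapply(split(net, net$regulator), function(ed) {
    ed <- ed[!duplicated(ed$target_c), , drop = FALSE]
    regulon <- intersect(ed$target_c, universe)
    K <- length(regulon)
    if (K < min_regulon) return(NULL)
    ed <- ed[ed$target_c %in% regulon, , drop = FALSE]
    hit <- intersect(regulon, sig)
    k <- length(hit)
    ed_sig <- ed[ed$target_c %in% hit, , drop = FALSE]
    cons <- sum((ed_sig$mode == "Activation" & ed_sig$target_c %in% up) |
                (ed_sig$mode == "Repression" & ed_sig$target_c %in% down))
    incons <- sum((ed_sig$mode == "Activation" & ed_sig$target_c %in% down) |
                  (ed_sig$mode == "Repression" & ed_sig$target_c %in% up))
    unk <- sum(ed_sig$mode == "Unknown")
    z <- if (cons + incons > 0) (cons - incons) / sqrt(cons + incons) else 0
    data.frame(
      regulator = ed$regulator[1], K = K, k = k, n = n, N = N,
      n_consistent = cons, n_inconsistent = incons, n_unknown = unk,
      activation_z = z,
      p = if (n > 0) hypergeometric_tail(k, K, n, N) else 1,
      state = if (z > 2) "activated" else if (z < -2) "inhibited" else "enriched-only",
      overlap_genes = paste(sort(hit), collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(regulator = character(), K = integer(), k = integer(),
                      n = integer(), N = integer(), n_consistent = integer(),
                      n_inconsistent = integer(), n_unknown = integer(),
                      activation_z = numeric(), p = numeric(), adj_p = numeric(),
                      state = character(), overlap_genes = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p)
  out <- out[order(out$p, out$regulator), ]
  out <- out[c("regulator", "K", "k", "n", "N", "n_consistent",
               "n_inconsistent", "n_unknown", "activation_z", "p", "adj_p",
               "state", "overlap_genes")]
  rownames(out) <- NULL
  out
}

#' Spatial (per-chromosome) enrichment
#'
#' Three families of two-sided Fisher tests per chromosome, each BH-corrected
#' across chromosomes:
#' \describe{
#'   \item{expression-bias}{expressed vs not, on vs off the chromosome,
#'     among all annotated genes ("expressed" = mean expression above
#'     `expressed_threshold`).}
#'   \item{de-bias}{differential (up or down) vs not, among expressed genes.}
#'   \item{direction-bias}{up vs down, among differential genes.}
#' }
#' Genes without a chromosome annotation are excluded from all families.
#'
#' @param master A master gene table.
#' @param comparison Comparison name.
#' @param expressed_threshold Mean-expression cut-off defining "expressed"
#'   (default 1, in the units of the expression matrix).
#' @return data.frame: `chromosome`, `family`, `a`, `b`, `c`, `d` (on-chrom
#'   positive, on-chrom negative, off-chrom positive, off-chrom negative),
#'   `p`, `adj_p`.
#' @export
run_spatial <- function(master, comparison, expressed_threshold = 1) {
  keep <- !is.na(master$chromosome) & nzchar(master$chromosome)
  if (!any(keep)) evi_abort("no gene has a chromosome annotation")
  chrom <- master$chromosome[keep]
  expr_mean <- rowMeans(master_expr(master))[keep]
  calls <- master_calls(master, comparison)[keep]
  expressed <- expr_mean > expressed_threshold
  de <- calls %in% c("up", "down")
  up <- calls == "up"

  empty_family <- data.frame(chromosome = character(), family = character(),
                             a = integer(), b = integer(), c = integer(),
                             d = integer(), p = numeric(), adj_p = numeric(),
                             stringsAsFactors = FALSE)
  family_rows <- function(family, universe_mask, positive_mask) {
    chr_u <- chrom[universe_mask]
    pos <- positive_mask[universe_mask]
    chrs <- unique(chr_u)
    chrs <- chrs[order(chrs)]
    if (!length(chrs)) return(empty_family)
    rows <- lapply(chrs, function(cc) {
      on <- chr_u == cc
      a <- sum(on & pos); b <- sum(on & !pos)
      c_ <- sum(!on & pos); d <- sum(!on & !pos)
      data.frame(chromosome = cc, family = family,
                 a = a, b = b, c = c_, d = d,
                 p = fisher_exact_two_sided(a, b, c_, d),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$adj_p <- bh_adjust(out$p)
    out
  }

  res <- rbind(
    family_rows("expression-bias", rep(TRUE, length(chrom)), expressed),
    family_rows("de-bias", expressed, de),
    family_rows("direction-bias", de, up)
  )
  rownames(res) <- NULL
  res
}

#' Overlap between two gene lists
#'
#' Size, fold-enrichment over the expectation for independent lists, and a
#' hypergeometric p-value for the overlap of two gene lists in a common
#' universe.
#'
#' @param list_a,list_b Character vectors of gene symbols.
#' @param universe Background symbols (both lists are intersected with it).
#' @return One-row data.frame: `n_a`, `n_b`, `overlap`, `N`, `expected`,
#'   `enrichment`, `p`.
#' @export
run_overlap <- function(list_a, list_b, universe) {
  universe <- unique(canon_symbol(universe))
  a <- intersect(unique(canon_symbol(list_a)), universe)
  b <- intersect(unique(canon_symbol(list_b)), universe)
  N <- length(universe)
  k <- length(intersect(a, b))
  expected <- length(a) * length(b) / N
  data.frame(
    n_a = length(a), n_b = length(b), overlap = k, N = N,
    expected = expected,
    enrichment = if (expected > 0) k / expected else 0,
    p = hypergeometric_tail(k, length(a), length(b), N)
  )
}

#' Shared-genes network of enrichment hits
#'
#' Nodes are the significant rows (adjusted p below `adj_p_cut`) of an ORA or
#' URA result; node size is the overlap count and intensity -log10(p). An
#' undirected edge joins two nodes when they share more than 50% of their
#' genes, the denominator being the smaller of the two overlap-gene sets.
#'
#' @param results data.frame from [run_ora()] or [run_ura()] (needs columns
#'   `p`, `adj_p`, `overlap_genes` and `set_name` or `regulator`).
#' @param adj_p_cut Significance cut-off (default 0.05).
#' @param share_frac Edge threshold on the shared fraction (default 0.5,
#'   strict inequality).
#' @return List with `nodes` (name, size, intensity) and `edges`
#'   (from, to, shared), class `gene_network`.
#' @export
build_shared_gene_network <- function(results, adj_p_cut = 0.05, share_frac = 0.5) {
  name_col <- if ("set_name" %in% names(results)) "set_name" else "regulator"
  sig <- results[!is.na(results$adj_p) & results$adj_p < adj_p_cut, , drop = FALSE]
  genes <- lapply(strsplit(sig$overlap_genes, ",", fixed = TRUE),
                  function(g) g[nzchar(g)])
  nodes <- data.frame(
    name = sig[[name_col]],
    size = lengths(genes),
    intensity = -log10(pmax(sig$p, .Machine$double.xmin)),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(from = character(), to = character(), shared = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(nodes) >= 2) {
    for (i in seq_len(nrow(nodes) - 1)) {
      for (j in (i + 1):nrow(nodes)) {
        shared <- length(intersect(genes[[i]], genes[[j]]))
        denom <- min(length(genes[[i]]), length(genes[[j]]))
        if (denom > 0 && shared / denom > share_frac) {
          edges <- rbind(edges, data.frame(from = nodes$name[i],
                                           to = nodes$name[j],
                                           shared = shared,
                                           stringsAsFactors = FALSE))
        }
      }
    }
  }
  structure(list(nodes = nodes, edges = edges), class = "gene_network")
}
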