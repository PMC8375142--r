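# Differential expression signatures: genes are binned by their
# per-comparison call profile, each bin is summarised by a meta-gene (the
# per-sample median of member z-scores), and bins are then iteratively
# merged while any two meta-genes correlate above a Spearman threshold.

#' Bin genes by differential expression profile
#'
#' One bin per distinct call profile (e.g. up in comparison 1 and down in
#' comparison 2) among genes significant in at least one comparison; genes
#' that are `ns`/`untested` everywhere are excluded.
#'
#' @param master A master gene table with computed calls.
#' @param comparisons Character vector of comparison names; defaults to all
#'   comparisons in the master table.
#' @return A `profile_bins` object: list of bins, each with `label`,
#'   `profile` (named call vector), `genes` and `meta_gene`.
#' @export
bin_profiles <- function(master, comparisons = NULL) {
  comparisons <- comparisons %||% names(master_comparisons(master))
  if (!length(comparisons)) evi_abort("no comparisons available for binning")
  calls <- sapply(comparisons, function(cmp) {
    cl <- master_calls(master, cmp)
    cl[cl == "untested"] <- "ns"
    cl
  })
  calls <- matrix(calls, ncol = length(comparisons),
                  dimnames = list(master$gene_id, comparisons))
  sig <- rowSums(calls == "up" | calls == "down") > 0
  if (!any(sig)) {
    return(structure(list(), comparisons = comparisons, class = "profile_bins"))
  }
  calls <- calls[sig, , drop = FALSE]
  labels <- apply(calls, 1, paste, collapse = "_")
  bins <- lapply(split(rownames(calls), labels), function(genes) {
    profile <- stats::setNames(calls[genes[1], ], comparisons)
    list(label = paste(profile, collapse = "_"), profile = profile,
         genes = genes, meta_gene = compute_metagene(genes, master))
  })
  bins <- bins[order(names(bins))]
  structure(unname(bins), comparisons = comparisons, class = "profile_bins")
}

#' Meta-gene of a gene group
#'
#' The per-sample median of the member genes' z-scores; the one-vector
#' summary of a profile bin or signature.
#'
#' @param genes Character vector of gene ids (must be in the master table).
#' @param master A master gene table.
#' @return Named numeric vector, one entry per sample.
#' @export
compute_metagene <- function(genes, master) {
  if (!length(genes)) evi_abort("meta-gene of an empty gene set")
  z <- master_z(master)
  missing <- setdiff(genes, rownames(z))
  if (length(missing)) evi_abort("gene(s) not in master table: %s",
                                 paste(utils::head(missing, 3), collapse = ", "))
  apply(z[genes, , drop = FALSE], 2, stats::median)
}

#' Merge profile bins into differential expression signatures
#'
#' Iteratively merges the pair of current meta-genes with the highest
#' Spearman correlation, recomputing the merged meta-gene from the union of
#' member genes, until no pair correlates above `scc_threshold`. With a
#' threshold of 1 no merge is possible (maximal resolution). Ties on the
#' maximal correlation are broken by the lexicographically first pair of
#' concatenated profile labels. Needs at least 3 samples; with fewer the
#' bins are returned unmerged with a warning.
#'
#' @param bins A `profile_bins` object (or the `signatures` of a previous
#'   run, which is idempotent).
#' @param master The master gene table the bins were computed from.
#' @param scc_threshold Spearman threshold in \[-1, 1\] above which (strictly)
#'   two meta-genes are merged (default 0.9).
#' @return A `signature_set`: list with `signatures` (each: `id`, `genes`,
#'   `meta_gene`, `source_profiles`), `merge_log` (data.frame: `first`,
#'   `second`, `scc`) and `scc_threshold`. Signatures are ranked by
#'   descending member count (id 1 = largest).
#' @export
merge_signatures <- function(bins, master, scc_threshold = 0.9) {
  if (scc_threshold < -1 || scc_threshold > 1) {
    evi_abort("scc_threshold must lie in [-1, 1]")
  }
  work <- lapply(bins, function(b) {
    list(label = b$label, genes = b$genes, meta_gene = b$meta_gene,
         source_profiles = b$source_profiles %||% list(b$label))
  })
  merge_log <- data.frame(first = character(), second = character(),
                          scc = numeric(), stringsAsFactors = FALSE)
  n_samples <- if (length(work)) length(work[[1]]$meta_gene) else 0
  can_merge <- length(work) >= 2 && n_samples >= 3
  if (length(work) >= 2 && n_samples < 3) {
    evi_warn("fewer than 3 samples: meta-gene correlation undefined, no merging")
  }

  while (can_merge && length(work) >= 2) {
    k <- length(work)
    best <- NULL; best_scc <- -Inf; best_key <- NULL
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        scc <- spearman(work[[i]]$meta_gene, work[[j]]$meta_gene)
        if (is.na(scc)) next  # constant meta-gene: never merged
        key <- paste(sort(c(work[[i]]$label, work[[j]]$label)), collapse = "+")
        if (scc > best_scc || (scc == best_scc && !is.null(best_key) && key < best_key)) {
          best_scc <- scc; best <- c(i, j); best_key <- key
        }
      }
    }
    if (is.null(best) || !(best_scc > scc_threshold)) break
    i <- best[1]; j <- best[2]
    genes <- union(work[[i]]$genes, work[[j]]$genes)
    merged <- list(
      label = best_key,
      genes = genes,
      meta_gene = compute_metagene(genes, master),
      source_profiles = c(work[[i]]$source_profiles, work[[j]]$source_profiles)
    )
    merge_log <- rbind(merge_log, data.frame(
      first = work[[i]]$label, second = work[[j]]$label, scc = best_scc,
      stringsAsFactors = FALSE))
    work <- c(work[-c(i, j)], list(merged))
  }

  ord <- order(-lengths(lapply(work, `[[`, "genes")),
               vapply(work, `[[`, character(1), "label"))
  signatures <- Map(function(w, id) {
    list(id = id, label = w$label, genes = w$genes, meta_gene = w$meta_gene,
         source_profiles = w$source_profiles)
  }, work[ord], seq_along(ord))
  structure(list(signatures = unname(signatures), merge_log = merge_log,
                 scc_threshold = scc_threshold),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature_set: %d signature(s), %d merge(s), threshold %.3g\n",
              length(x$signatures), nrow(x$merge_log), x$scc_threshold))
  for (s in x$signatures) {
    cat(sprintf("  %d: %d genes [%s]\n", s$id, length(s$genes), s$label))
  }
  invisible(x)
}

# Serialisers used by the MDE workflow ---------------------------------

signature_assignments <- function(sigs) {
  do.call(rbind, lapply(sigs$signatures, function(s) {
    data.frame(gene_id = s$genes, signature = s$id, stringsAsFactors = FALSE)
  })) %||% data.frame(gene_id = character(), signature = integer())
}

signature_metagenes <- function(sigs) {
  if (!length(sigs$signatures)) {
    return(data.frame(signature = integer()))
  }
  m <- do.call(rbind, lapply(sigs$signatures, `[[`, "meta_gene"))
  data.frame(signature = vapply(sigs$signatures, `[[`, integer(1), "id"),
             m, check.names = FALSE)
}
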