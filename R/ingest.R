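# Readers and validators for the five input file kinds, and assembly of the
# master gene table that every workflow consumes.
#
# File contracts:
#   sample sheet   TSV, header, >= 2 columns: sample id, group label
#   EM             TSV, first column gene id, remaining columns samples
#   DE table       TSV with columns mappable to gene id / log2fc / p / adj p
#   background     TSV: gene_id, symbol, chromosome[, biotype]
#   GMT            name TAB description TAB member TAB member ...
#   TRRUST         regulator TAB target TAB mode TAB references

#' Read a sample sheet
#'
#' Tab-delimited, with a header; the first two columns (or columns named
#' `sample` and `group`) map samples to group labels. Group order is the
#' order of first appearance, overridable downstream.
#'
#' @param path Path to the TSV file.
#' @return A `sample_sheet` object: list with `samples` (data.frame:
#'   `sample_id`, `group`) and `group_order`.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) evi_abort("sample sheet not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  if (nrow(df) == 0) evi_abort("sample sheet is empty: %s", path)
  if (ncol(df) < 2) evi_abort("sample sheet needs >= 2 columns (sample, group)")
  nm <- tolower(names(df))
  si <- if ("sample" %in% nm) which(nm == "sample")[1] else 1L
  gi <- if ("group" %in% nm) which(nm == "group")[1] else 2L
  sample_sheet(trimws(df[[si]]), trimws(df[[gi]]))
}

#' Construct a sample sheet from vectors
#'
#' @param sample_ids Character vector of unique, non-empty sample ids.
#' @param groups Group label per sample.
#' @param group_order Optional explicit group ordering (must be a permutation
#'   of the distinct labels); default is first-appearance order.
#' @return A `sample_sheet` object.
#' @export
sample_sheet <- function(sample_ids, groups, group_order = NULL) {
  if (length(sample_ids) != length(groups)) {
    evi_abort("sample ids and groups differ in length")
  }
  if (any(!nzchar(sample_ids))) evi_abort("empty sample id")
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup)) evi_abort("duplicate sample id(s): %s", paste(dup, collapse = ", "))
  if (any(!nzchar(groups))) evi_abort("empty group label")
  first_seen <- unique(groups)
  if (is.null(group_order)) {
    group_order <- first_seen
  } else if (!setequal(group_order, first_seen) ||
             length(group_order) != length(first_seen)) {
    evi_abort("group_order must be a permutation of the group labels")
  }
  structure(
    list(samples = data.frame(sample_id = sample_ids, group = groups,
                              stringsAsFactors = FALSE),
         group_order = group_order),
    class = "sample_sheet"
  )
}

#' @export
print.sample_sheet <- function(x, ...) {
  cat(sprintf("sample_sheet: %d samples, %d groups (%s)\n",
              nrow(x$samples), length(x$group_order),
              paste(x$group_order, collapse = ", ")))
  invisible(x)
}

#' Read a normalized expression matrix (EM file)
#'
#' TSV; first column gene id, remaining columns one per sample. Values must
#' be numeric and non-negative (normalized expression in any unit: FPKM,
#' TPM, rlog, ...). Duplicate gene ids keep the first occurrence, with a
#' warning.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix, genes in rows (rownames = gene ids).
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) evi_abort("expression matrix not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2) evi_abort("expression matrix needs gene id + >= 1 sample column")
  gene_ids <- trimws(df[[1]])
  m <- matrix(NA_real_, nrow(df), ncol(df) - 1,
              dimnames = list(NULL, names(df)[-1]))
  for (j in 2:ncol(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !is.na(df[[j]]) & df[[j]] != "NA")
    if (length(bad)) {
      evi_abort("non-numeric expression value '%s' at row %d, column '%s'",
                df[[j]][bad[1]], bad[1], names(df)[j])
    }
    if (anyNA(v)) {
      evi_abort("missing expression value at row %d, column '%s'",
                which(is.na(v))[1], names(df)[j])
    }
    m[, j - 1] <- v
  }
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    evi_abort("negative expression value at gene '%s', sample '%s'",
              gene_ids[idx[1]], colnames(m)[idx[2]])
  }
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    evi_warn("duplicate gene id(s) in EM (first occurrence kept): %s",
             paste(utils::head(dup, 5), collapse = ", "))
    keep <- !duplicated(gene_ids)
    m <- m[keep, , drop = FALSE]
    gene_ids <- gene_ids[keep]
  }
  rownames(m) <- gene_ids
  m
}

#' Default differential-table column mappings
#'
#' Synonym sets used to locate the gene id, log2 fold change, p-value and
#' adjusted p-value columns in tables produced by common tools (DESeq2,
#' edgeR, ...). Override any entry to support other headers.
#'
#' @param gene_id,log2fc,p,adj_p Character vectors of accepted header names
#'   (matched case-insensitively; the first match wins).
#' @return Named list of synonym vectors.
#' @export
de_columns <- function(gene_id = c("gene_id", "gene", "id", "row.names", "x"),
                       log2fc = c("log2fc", "log2foldchange", "logfc", "log2_fold_change"),
                       p = c("p", "pvalue", "p_value", "p.value"),
                       adj_p = c("adj_p", "padj", "fdr", "adj.p.val", "adjp", "q_value", "qvalue")) {
  list(gene_id = gene_id, log2fc = log2fc, p = p, adj_p = adj_p)
}

#' Read a differential expression table (DE file)
#'
#' One row per gene with log2 fold change (positive = higher in the test
#' group), p-value and adjusted p-value. Missing statistics are retained as
#' NA; such genes are later called `untested`.
#'
#' @param path Path to the TSV file.
#' @param columns Column mapping, see [de_columns()].
#' @return data.frame with `gene_id`, `log2fc`, `p`, `adj_p`.
#' @export
read_differential_table <- function(path, columns = de_columns()) {
  if (!file.exists(path)) evi_abort("differential table not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  nm <- tolower(names(df))
  pick <- function(field) {
    hit <- which(nm %in% tolower(columns[[field]]))
    if (!length(hit)) {
      if (field == "gene_id") return(1L)  # fall back to first column
      evi_abort("differential table '%s': no column for %s (accepted: %s)",
                path, field, paste(columns[[field]], collapse = ", "))
    }
    hit[1]
  }
  out <- data.frame(
    gene_id = trimws(as.character(df[[pick("gene_id")]])),
    log2fc = suppressWarnings(as.numeric(df[[pick("log2fc")]])),
    p = suppressWarnings(as.numeric(df[[pick("p")]])),
    adj_p = suppressWarnings(as.numeric(df[[pick("adj_p")]])),
    stringsAsFactors = FALSE
  )
  for (f in c("p", "adj_p")) {
    bad <- which(!is.na(out[[f]]) & (out[[f]] < 0 | out[[f]] > 1))
    if (length(bad)) {
      evi_abort("differential table '%s': %s = %g out of [0, 1] at gene '%s'",
                path, f, out[[f]][bad[1]], out$gene_id[bad[1]])
    }
  }
  if (anyDuplicated(out$gene_id)) {
    dup <- unique(out$gene_id[duplicated(out$gene_id)])
    evi_warn("duplicate gene id(s) in DE table (first kept): %s",
             paste(utils::head(dup, 5), collapse = ", "))
    out <- out[!duplicated(out$gene_id), , drop = FALSE]
  }
  n_na <- sum(is.na(out$adj_p))
  if (n_na > 0) {
    evi_warn("%d gene(s) with missing adjusted p in '%s' will be called 'untested'",
             n_na, basename(path))
  }
  rownames(out) <- NULL
  out
}

#' Read a genome background / annotation file
#'
#' TSV with gene id, symbol and chromosome name (plus optional biotype), as
#' exported from Biomart-style annotation services. Genes with an empty
#' chromosome are excluded from the spatial analysis only.
#'
#' @param path Path to the TSV file.
#' @return data.frame `gene_id`, `symbol`, `chromosome`, `biotype`.
#' @export
read_background <- function(path) {
  if (!file.exists(path)) evi_abort("background file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 3) evi_abort("background file needs >= 3 columns (gene id, symbol, chromosome)")
  nm <- tolower(names(df))
  pick <- function(syn, default) {
    hit <- which(nm %in% syn)
    if (length(hit)) hit[1] else default
  }
  gi <- pick(c("gene_id", "gene stable id", "ensembl_gene_id"), 1L)
  sy <- pick(c("symbol", "gene name", "gene_name", "external_gene_name"), 2L)
  ch <- pick(c("chromosome", "chromosome/scaffold name", "chromosome_name", "chr"), 3L)
  bt <- pick(c("biotype", "gene type", "gene_biotype"), NA_integer_)
  out <- data.frame(
    gene_id = trimws(df[[gi]]),
    symbol = trimws(df[[sy]]),
    chromosome = trimws(df[[ch]]),
    biotype = if (is.na(bt)) NA_character_ else trimws(df[[bt]]),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$gene_id)) {
    evi_warn("duplicate gene id(s) in background (first kept)")
    out <- out[!duplicated(out$gene_id), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Read a gene-set database in GMT format
#'
#' Each line: set name, description, then member gene symbols, tab-separated.
#' Sets with no members are dropped with a warning; duplicate members within
#' a set are de-duplicated.
#'
#' @param path Path to the GMT file.
#' @return A `gene_set_db`: named list of character vectors (members), with
#'   a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) evi_abort("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3 || !any(nzchar(trimws(f[-(1:2)])))) {
      evi_warn("GMT set '%s' has no members; dropped", f[1])
      next
    }
    members <- unique(trimws(f[-(1:2)]))
    members <- members[nzchar(members)]
    sets[[f[1]]] <- members
    desc[f[1]] <- f[2]
  }
  if (anyDuplicated(names(sets))) evi_abort("duplicate set name(s) in GMT: %s", path)
  structure(sets, descriptions = desc, class = "gene_set_db")
}

#' Read a regulator network in TRRUST format
#'
#' Tab-delimited rows: regulator symbol, target symbol, mode of regulation
#' (`Activation`, `Repression` or `Unknown`), reference ids (ignored).
#' Unrecognised mode strings map to `Unknown` with a warning; duplicate
#' (regulator, target) pairs keep the first mode.
#'
#' @param path Path to the TSV file (no header).
#' @return data.frame `regulator`, `target`, `mode`.
#' @export
read_trrust <- function(path) {
  if (!file.exists(path)) evi_abort("regulator network not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", header = FALSE,
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 3) evi_abort("regulator network needs >= 3 columns")
  mode <- trimws(df[[3]])
  known <- mode %in% c("Activation", "Repression", "Unknown")
  if (any(!known)) {
    evi_warn("%d edge(s) with unrecognised mode mapped to 'Unknown' (e.g. '%s')",
             sum(!known), mode[!known][1])
    mode[!known] <- "Unknown"
  }
  out <- data.frame(regulator = trimws(df[[1]]), target = trimws(df[[2]]),
                    mode = mode, stringsAsFactors = FALSE)
  out <- out[!duplicated(out[c("regulator", "target")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Define one differential comparison
#'
#' @param name Short label used in file names and column prefixes.
#' @param test_group,reference_group Group labels; positive log2 fold change
#'   means higher in the test group.
#' @param de_table data.frame as returned by [read_differential_table()].
#' @param adj_p_threshold Significance threshold on the adjusted p (default 0.05).
#' @param abs_log2fc_threshold Minimum absolute log2 fold change (default 1).
#' @return A `comparison_spec` object.
#' @export
comparison_spec <- function(name, test_group, reference_group, de_table,
                            adj_p_threshold = 0.05, abs_log2fc_threshold = 1) {
  if (!nzchar(name)) evi_abort("comparison needs a name")
  if (adj_p_threshold <= 0 || abs_log2fc_threshold <= 0) {
    evi_abort("comparison '%s': thresholds must be > 0", name)
  }
  structure(
    list(name = name, test_group = test_group, reference_group = reference_group,
         de_table = de_table, adj_p_threshold = adj_p_threshold,
         abs_log2fc_threshold = abs_log2fc_threshold),
    class = "comparison_spec"
  )
}

#' Assemble the master gene table
#'
#' Joins expression, per-group means, per-gene z-scores (over all samples),
#' annotation and per-comparison differential statistics into the single
#' table every workflow reads. Calls per comparison: `up` if adjusted
#' p < threshold and log2fc > +threshold, `down` if adjusted p < threshold
#' and log2fc < -threshold, `ns` otherwise, and `untested` when the gene is
#' absent from that DE table or its adjusted p is missing.
#'
#' @param sheet A [sample_sheet()].
#' @param em Genes x samples matrix from [read_expression_matrix()].
#' @param comparisons List of [comparison_spec()] objects.
#' @param background data.frame from [read_background()] (optional; genes
#'   missing from it carry their gene id as symbol and no chromosome).
#' @return A `master_gene_table`: data.frame with attributes `sample_ids`,
#'   `sample_groups`, `group_order`, `comparisons`.
#' @export
build_master_table <- function(sheet, em, comparisons = list(), background = NULL) {
  stopifnot(inherits(sheet, "sample_sheet"))
  ids <- sheet$samples$sample_id
  if (!setequal(colnames(em), ids)) {
    evi_abort("EM samples do not match the sample sheet (missing: %s; extra: %s)",
              paste(setdiff(ids, colnames(em)), collapse = ", ") ,
              paste(setdiff(colnames(em), ids), collapse = ", "))
  }
  em <- em[, ids, drop = FALSE]
  genes <- rownames(em)
  groups <- sheet$samples$group
  names(groups) <- ids

  df <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  if (!is.null(background)) {
    i <- match(genes, background$gene_id)
    df$symbol <- ifelse(is.na(i), genes, background$symbol[i])
    df$chromosome <- ifelse(is.na(i), NA_character_, background$chromosome[i])
    df$chromosome[!is.na(df$chromosome) & !nzchar(df$chromosome)] <- NA_character_
    df$biotype <- if (all(is.na(background$biotype))) NA_character_ else
      ifelse(is.na(i), NA_character_, background$biotype[i])
  } else {
    df$symbol <- genes
    df$chromosome <- NA_character_
    df$biotype <- NA_character_
  }

  expr <- as.data.frame(em)
  names(expr) <- paste0("expr.", ids)
  df <- cbind(df, expr)

  for (g in sheet$group_order) {
    cols <- ids[groups == g]
    df[[paste0("mean.", g)]] <- rowMeans(em[, cols, drop = FALSE])
  }

  mu <- rowMeans(em)
  sdv <- apply(em, 1, stats::sd)
  z <- (em - mu) / ifelse(sdv == 0, 1, sdv)
  z[sdv == 0, ] <- 0
  zdf <- as.data.frame(z)
  names(zdf) <- paste0("z.", ids)
  df <- cbind(df, zdf)

  cmp_meta <- list()
  for (cmp in comparisons) {
    stopifnot(inherits(cmp, "comparison_spec"))
    if (!cmp$test_group %in% sheet$group_order ||
        !cmp$reference_group %in% sheet$group_order) {
      evi_abort("comparison '%s': group not in the sample sheet", cmp$name)
    }
    de <- cmp$de_table
    i <- match(genes, de$gene_id)
    if (all(is.na(i))) {
      evi_abort("comparison '%s': no genes shared between EM and DE table", cmp$name)
    }
    lfc <- de$log2fc[i]; p <- de$p[i]; ap <- de$adj_p[i]
    call <- rep("ns", length(genes))
    call[is.na(i) | is.na(ap) | is.na(lfc)] <- "untested"
    sig <- !is.na(ap) & !is.na(lfc) & ap < cmp$adj_p_threshold
    call[sig & lfc > cmp$abs_log2fc_threshold] <- "up"
    call[sig & lfc < -cmp$abs_log2fc_threshold] <- "down"
    df[[paste0(cmp$name, ".log2fc")]] <- lfc
    df[[paste0(cmp$name, ".p")]] <- p
    df[[paste0(cmp$name, ".adj_p")]] <- ap
    df[[paste0(cmp$name, ".call")]] <- call
    cmp_meta[[cmp$name]] <- cmp[c("name", "test_group", "reference_group",
                                  "adj_p_threshold", "abs_log2fc_threshold")]
  }

  structure(df,
            sample_ids = ids,
            sample_groups = groups,
            group_order = sheet$group_order,
            comparisons = cmp_meta,
            class = c("master_gene_table", "data.frame"))
}

# accessors -------------------------------------------------------------

#' @export
print.master_gene_table <- function(x, ...) {
  cat(sprintf("master_gene_table: %d genes, %d samples, %d comparison(s)\n",
              nrow(x), length(attr(x, "sample_ids")),
              length(attr(x, "comparisons"))))
  invisible(x)
}

master_samples <- function(master) attr(master, "sample_ids")
master_groups <- function(master) attr(master, "sample_groups")
master_group_order <- function(master) attr(master, "group_order")
master_comparisons <- function(master) attr(master, "comparisons")

master_expr <- function(master) {
  ids <- master_samples(master)
  m <- as.matrix(master[paste0("expr.", ids)])
  dimnames(m) <- list(master$gene_id, ids)
  m
}

master_z <- function(master) {
  ids <- master_samples(master)
  m <- as.matrix(master[paste0("z.", ids)])
  dimnames(m) <- list(master$gene_id, ids)
  m
}

master_calls <- function(master, comparison) {
  col <- paste0(comparison, ".call")
  if (!col %in% names(master)) evi_abort("unknown comparison '%s'", comparison)
  stats::setNames(master[[col]], master$gene_id)
}

# Gene symbols (canonicalised) significant in a comparison; direction one of
# "all", "up", "down".
significant_symbols <- function(master, comparison, direction = "all") {
  calls <- master_calls(master, comparison)
  want <- switch(direction, all = c("up", "down"), up = "up", down = "down",
                 evi_abort("unknown direction '%s'", direction))
  canon_symbol(master$symbol[calls %in% want & !is.na(master$symbol)])
}

#' Write / read the master gene table
#'
#' TSV serialisation with full double precision: re-reading reproduces the
#' written numeric values exactly. Comparison and sample metadata are stored
#' in a JSON sidecar next to the table.
#'
#' @param master A `master_gene_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly (writer); a `master_gene_table` (reader).
#' @export
write_master_table <- function(master, path) {
  write_tsv_exact(as.data.frame(master), path)
  meta <- list(
    sample_ids = master_samples(master),
    sample_groups = as.list(master_groups(master)),
    group_order = master_group_order(master),
    comparisons = master_comparisons(master),
    column_classes = as.list(vapply(master, function(x) class(x)[1],
                                    character(1)))
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_master_table
#' @export
read_master_table <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  classes <- unlist(meta$column_classes)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = "NA",
                          colClasses = unname(classes))
  cmp <- lapply(meta$comparisons, function(x) {
    x <- as.list(x)
    for (f in c("adj_p_threshold", "abs_log2fc_threshold")) {
      x[[f]] <- as.numeric(x[[f]])   # JSON integers back to doubles
    }
    x
  })
  groups <- unlist(meta$sample_groups)
  structure(df,
            sample_ids = meta$sample_ids,
            sample_groups = groups,
            group_order = meta$group_order,
            comparisons = cmp,
            class = c("master_gene_table", "data.frame"))
}
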