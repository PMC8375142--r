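# The three workflows (NE / DE / MDE): each computes its statistics, writes
# per-plot data files, composes and executes a standalone script per plot,
# and returns artifact records for the report, the combined script and the
# run manifest.

# ggplot2-style categorical palette, stable for a given group order
group_palette <- function(groups) {
  n <- length(groups)
  h <- seq(15, 375, length.out = n + 1)[seq_len(n)]
  stats::setNames(grDevices::hcl(h = h, c = 100, l = 65), groups)
}

call_colours <- c(up = "#B2182B", down = "#2166AC", ns = "black",
                  untested = "grey60")

# literal R expression for a named colour vector, embedded into scripts
deparse_palette <- function(x) {
  if (!length(x)) return("character(0)")
  paste0("c(", paste(sprintf('"%s" = "%s"', names(x), unname(x)),
                     collapse = ", "), ")")
}

quote_str <- function(x) gsub('"', "'", x, fixed = TRUE)

default_tags <- function(family) {
  switch(family,
    bar = list(fill_values = 'c("value" = "grey40")', fill_lab = "",
               x_lab = "", y_lab = "", legend_pos = "none",
               flip_line = "# orientation: vertical"),
    scatter = list(colour_values = 'c("all" = "black")', colour_lab = "",
                   x_lab = "", y_lab = "", subtitle = "",
                   legend_pos = "right", extra_lines = ""),
    histogram = list(bins = "40", x_lab = "value"),
    density = list(colour_values = 'c("all" = "black")',
                   colour_lab = "sample", x_lab = "value"),
    box = list(fill_values = 'c("all" = "grey70")', fill_lab = "group",
               x_lab = "", y_lab = "z-score"),
    violin = list(fill_values = 'c("all" = "grey70")', x_lab = "",
                  y_lab = "expression"),
    heatmap = list(fill_limits = "c(-1, 1)", fill_lab = "z-score",
                   row_text = "element_blank()"),
    table = list(),
    network = list(size_lab = "genes"),
    list()
  )
}

new_emitter <- function(out_dir, bin, dpi = 300, formats = c("png", "svg"),
                        execute = TRUE) {
  for (d in c("data", "scripts", "plots")) {
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  env <- new.env(parent = emptyenv())
  env$out_dir <- out_dir
  env$instance <- basename(out_dir)
  env$bin <- bin
  env$dpi <- dpi
  env$formats <- formats
  env$execute <- execute
  env$artifacts <- list()
  env
}

formats_literal <- function(formats) {
  paste0("c(", paste(sprintf('"%s"', formats), collapse = ", "), ")")
}

emit_artifact <- function(em, type_id, data, tags = list(), sub = NULL,
                          note = NULL) {
  reg <- plot_registry()
  row <- reg[reg$type_id == type_id, , drop = FALSE]
  if (nrow(row) != 1) evi_abort("unknown plot type '%s'", type_id)
  id <- paste(c(em$instance, type_id, sub), collapse = "_")
  data_file <- file.path(em$out_dir, "data", paste0(id, ".tsv"))
  script_file <- file.path(em$out_dir, "scripts", paste0(id, ".R"))
  write_tsv_exact(data, data_file)

  title <- quote_str(paste(c(row$title, sub), collapse = " - "))
  context <- utils::modifyList(
    c(default_tags(row$family),
      list(title = title,
           type_id = type_id,
           script_name = paste0(id, ".R"),
           data_file = paste0("../data/", id, ".tsv"),
           image_base = paste0("../plots/", id),
           width = row$width, height = row$height,
           dpi = em$dpi, formats = formats_literal(em$formats),
           flip_line = if (row$flip == "yes") "p <- p + coord_flip()"
                       else "# orientation: vertical")),
    tags
  )
  writeLines(compose_script(type_id, em$bin, context), script_file)
  images <- file.path(em$out_dir, "plots", paste0(id, ".", em$formats))
  if (em$execute) {
    suppressWarnings(run_plot_script(script_file))
    missing <- images[!file.exists(images)]
    if (length(missing)) evi_abort("plot script '%s' produced no %s", id,
                                   paste(basename(missing), collapse = ", "))
  }
  art <- list(id = id, type_id = type_id, workflow = row$workflow,
              instance = em$instance,
              data_file = file.path("data", paste0(id, ".tsv")),
              script_file = file.path("scripts", paste0(id, ".R")),
              images = file.path("plots", paste0(id, ".", em$formats)),
              title = title,
              description = if (is.null(note)) row$description
                            else paste(row$description, note),
              legend = row$legend, methods = row$methods,
              context = context)
  em$artifacts[[id]] <- art
  invisible(art)
}

finish_instance <- function(em) {
  arts <- unname(em$artifacts)
  if (length(arts)) {
    shared_context <- list(
      title = paste("combined script:", em$instance),
      script_name = paste0(em$instance, "_all_plots.R"),
      dpi = em$dpi, formats = formats_literal(em$formats)
    )
    combined <- compose_workflow_script(arts, em$bin, shared_context)
    writeLines(combined, file.path(em$out_dir, "scripts",
                                   paste0(em$instance, "_all_plots.R")))
  }
  arts
}

# ---------------------------------------------------------------------------
# shared data builders

# long z-score matrix for a heatmap, rows ordered by `row_order`
heatmap_data <- function(z, row_order = NULL, col_order = NULL) {
  if (!is.null(row_order)) z <- z[row_order, , drop = FALSE]
  if (!is.null(col_order)) z <- z[, col_order, drop = FALSE]
  if (nrow(z) == 0) {
    return(data.frame(row = character(), col = character(), value = numeric()))
  }
  data.frame(
    row = rep(rownames(z), times = ncol(z)),
    col = rep(colnames(z), each = nrow(z)),
    value = as.vector(z),
    stringsAsFactors = FALSE
  )
}

symmetric_limits <- function(values) {
  m <- if (length(values)) max(abs(values), na.rm = TRUE) else 1
  if (!is.finite(m) || m == 0) m <- 1
  sprintf("c(%.6g, %.6g)", -m, m)
}

# cluster rows of a z matrix (UPGMA on 1 - SCC, mean reordering); rows with
# fewer than 2 entries or matrices with < 2 rows are returned unchanged
clustered_row_order <- function(z) {
  if (nrow(z) < 2) return(rownames(z))
  cl <- suppressWarnings(upgma_cluster(z))
  rownames(z)[cl$order]
}

# violin data: one row per (gene, sample), panelled by gene
violin_gene_data <- function(master, genes, samples, value = c("expr", "z")) {
  value <- match.arg(value)
  m <- if (value == "expr") master_expr(master) else master_z(master)
  groups <- master_groups(master)
  if (!length(genes)) {
    return(data.frame(x = character(), y = numeric(), panel = character()))
  }
  sym <- stats::setNames(master$symbol, master$gene_id)
  do.call(rbind, lapply(genes, function(g) {
    data.frame(x = unname(groups[samples]), y = m[g, samples],
               panel = unname(sym[g]), stringsAsFactors = FALSE)
  }))
}

# boxplot data for a symbol list: per-gene z by sample group
box_symbol_data <- function(master, symbols, samples) {
  idx <- match(canon_symbol(symbols), canon_symbol(master$symbol))
  idx <- idx[!is.na(idx)]
  groups <- master_groups(master)
  if (!length(idx)) {
    return(data.frame(x = character(), y = numeric(), fill = character()))
  }
  z <- master_z(master)[master$gene_id[idx], samples, drop = FALSE]
  data.frame(
    x = rep(master$symbol[idx], times = length(samples)),
    y = as.vector(z),
    fill = rep(unname(groups[samples]), each = length(idx)),
    stringsAsFactors = FALSE
  )
}

# circular-layout network data frame (nodes + edges in one table)
network_data <- function(net, label_max = 18) {
  nodes <- net$nodes
  n <- nrow(nodes)
  empty <- data.frame(element = character(), x = numeric(), y = numeric(),
                      xend = numeric(), yend = numeric(), label = character(),
                      size = numeric(), intensity = numeric(),
                      stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  ang <- pi / 2 - 2 * pi * (seq_len(n) - 1) / n
  pos <- data.frame(x = round(cos(ang), 6), y = round(sin(ang), 6))
  lab <- ifelse(nchar(nodes$name) > label_max,
                paste0(substr(nodes$name, 1, label_max - 1), "~"), nodes$name)
  nd <- data.frame(element = "node", x = pos$x, y = pos$y,
                   xend = NA_real_, yend = NA_real_, label = lab,
                   size = nodes$size, intensity = round(nodes$intensity, 6),
                   stringsAsFactors = FALSE)
  ed <- empty
  if (nrow(net$edges)) {
    i <- match(net$edges$from, nodes$name)
    j <- match(net$edges$to, nodes$name)
    ed <- data.frame(element = "edge", x = pos$x[i], y = pos$y[i],
                     xend = pos$x[j], yend = pos$y[j], label = NA_character_,
                     size = NA_real_, intensity = NA_real_,
                     stringsAsFactors = FALSE)
  }
  rbind(nd, ed)
}

top_hits_bar_data <- function(res, n_top, name_col, value, label, fill) {
  if (!nrow(res)) {
    return(data.frame(category = character(), value = numeric(),
                      fill = character(), label = character()))
  }
  top <- utils::head(res, n_top)
  data.frame(category = top[[name_col]], value = value(top),
             fill = fill(top), label = label(top), stringsAsFactors = FALSE)
}

placeholder_table <- function(msg) {
  data.frame(note = msg, stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------

#' Run the normalized expression (NE) workflow
#'
#' Expression-level overview of a set of groups: per-sample expression
#' distributions, PCA, sample-correlation (distance) analysis and highly
#' expressed gene analysis. Emits the NE plot registry with data files,
#' standalone scripts, images and a combined script.
#'
#' @param master A master gene table.
#' @param out_dir Workflow instance output directory (created).
#' @param groups Groups included (default: all, in sample-sheet order).
#' @param top_n Number of top genes in tables/violins (default 5; the
#'   violins show `top_n - 1` genes to keep panels readable).
#' @param bin Snippet bin (default: shipped).
#' @param dpi,formats Image resolution and formats.
#' @param execute Render images by executing each script (default TRUE).
#' @return List of artifact records (invisibly).
#' @export
run_ne <- function(master, out_dir, groups = NULL, top_n = 5,
                   bin = snippet_bin(), dpi = 300,
                   formats = c("png", "svg"), execute = TRUE) {
  groups <- groups %||% master_group_order(master)
  all_groups <- master_groups(master)
  samples <- master_samples(master)[all_groups %in% groups]
  if (!length(samples)) evi_abort("no samples in the requested groups")
  em <- new_emitter(out_dir, bin, dpi, formats, execute)
  pal <- group_palette(groups)
  sample_pal <- stats::setNames(unname(pal[all_groups[samples]]), samples)
  expr <- master_expr(master)[, samples, drop = FALSE]
  lx <- log10(expr + 1)

  # expression distributions (QC)
  dens <- data.frame(x = as.vector(lx),
                     group = rep(samples, each = nrow(lx)),
                     stringsAsFactors = FALSE)
  emit_artifact(em, "ne_density", dens,
                list(colour_values = deparse_palette(sample_pal),
                     x_lab = "log10(expression + 1)", colour_lab = "sample"))

  emit_artifact(em, "ne_sample_box",
                data.frame(x = rep(samples, each = nrow(lx)),
                           y = as.vector(lx),
                           fill = rep(unname(all_groups[samples]),
                                      each = nrow(lx)),
                           stringsAsFactors = FALSE),
                list(fill_values = deparse_palette(pal), fill_lab = "group",
                     x_lab = "", y_lab = "log10(expression + 1)"))

  # PCA
  pca <- pca_samples(expr)
  pct <- pca$percent_var
  emit_artifact(em, "ne_pca_variance",
                data.frame(category = paste0("PC", seq_along(pct)),
                           value = pct, fill = "variance",
                           label = sprintf("%.1f%%", pct),
                           stringsAsFactors = FALSE),
                list(fill_values = 'c("variance" = "grey40")',
                     x_lab = "component", y_lab = "% of variation explained"))
  scatter_pc <- function(type_id, i, j) {
    sc <- pca$scores
    have <- ncol(sc) - 1 >= j
    dat <- if (have) {
      data.frame(x = sc[[paste0("PC", i)]], y = sc[[paste0("PC", j)]],
                 colour = unname(all_groups[sc$sample_id]),
                 stringsAsFactors = FALSE)
    } else data.frame(x = numeric(), y = numeric(), colour = character())
    emit_artifact(em, type_id, dat,
                  list(colour_values = deparse_palette(pal),
                       colour_lab = "group",
                       x_lab = if (have) sprintf("PC%d (%.1f%%)", i, pct[i]) else sprintf("PC%d", i),
                       y_lab = if (have) sprintf("PC%d (%.1f%%)", j, pct[j]) else sprintf("PC%d", j)),
                  note = if (!have) "(not enough components for this plot)" else NULL)
  }
  scatter_pc("ne_pca_scatter_12", 1, 2)
  scatter_pc("ne_pca_scatter_34", 3, 4)

  # sample-to-sample Spearman correlation heatmap, clustered
  cc <- suppressWarnings(stats::cor(expr, method = "spearman"))
  cc[!is.finite(cc)] <- 0
  ord <- if (ncol(cc) >= 2) {
    cl <- upgma_cluster(1 - cc, is_distance = TRUE, row_means = rowMeans(cc))
    colnames(cc)[cl$order]
  } else colnames(cc)
  emit_artifact(em, "ne_correlation_heatmap",
                heatmap_data(cc[ord, ord, drop = FALSE]),
                list(fill_limits = "c(-1, 1)", fill_lab = "SCC",
                     row_text = "element_text(size = font.size * 0.7)"))

  # highly expressed gene analysis
  mean_cols <- paste0("mean.", groups)
  top_tab <- do.call(rbind, lapply(groups, function(g) {
    ord <- order(-master[[paste0("mean.", g)]], master$symbol)
    top <- master[utils::head(ord, top_n), c("symbol", mean_cols)]
    cbind(data.frame(group = g, stringsAsFactors = FALSE), top)
  }))
  names(top_tab) <- c("group", "symbol", paste0("mean ", groups))
  emit_artifact(em, "ne_top_genes_table", top_tab)

  last <- groups[length(groups)]
  ord <- order(-master[[paste0("mean.", last)]], master$symbol)
  top_genes <- master$gene_id[utils::head(ord, max(top_n - 1, 1))]
  emit_artifact(em, "ne_top_genes_violin",
                violin_gene_data(master, top_genes, samples, "expr"),
                list(fill_values = deparse_palette(pal),
                     x_lab = "", y_lab = "normalized expression"))

  invisible(finish_instance(em))
}

#' Run the differential expression (DE) workflow
#'
#' Full single-comparison analysis: differential counts, MA/volcano,
#' significant-gene heatmaps, top-gene tables and violins, per-chromosome
#' (spatial) analysis, over-representation analysis of all/up/down genes and
#' upstream regulator analysis, each with top-hit bars, expression boxplots
#' and shared-gene networks.
#'
#' @param master A master gene table.
#' @param comparison Comparison name (must exist in the master table).
#' @param out_dir Workflow instance output directory.
#' @param gmt_db Optional `gene_set_db` for ORA.
#' @param trrust Optional regulator network data.frame for URA.
#' @param top_n Top hits shown in bars/tables (default 5).
#' @param adj_p_cut Significance cut-off for network nodes (default 0.05).
#' @param expressed_threshold Mean-expression cut-off for the spatial
#'   expression-bias family (default 1).
#' @inheritParams run_ne
#' @return List of artifact records (invisibly).
#' @export
run_de <- function(master, comparison, out_dir, gmt_db = NULL, trrust = NULL,
                   top_n = 5, adj_p_cut = 0.05, expressed_threshold = 1,
                   bin = snippet_bin(), dpi = 300, formats = c("png", "svg"),
                   execute = TRUE) {
  cmp <- master_comparisons(master)[[comparison]]
  if (is.null(cmp)) evi_abort("unknown comparison '%s'", comparison)
  em <- new_emitter(out_dir, bin, dpi, formats, execute)
  all_groups <- master_groups(master)
  grp <- c(cmp$reference_group, cmp$test_group)
  samples <- master_samples(master)[all_groups %in% grp]
  pal <- group_palette(grp)
  calls <- master_calls(master, comparison)
  lfc <- master[[paste0(comparison, ".log2fc")]]
  p_raw <- master[[paste0(comparison, ".p")]]
  sig_mask <- calls %in% c("up", "down")
  sig_genes <- master$gene_id[sig_mask]
  z <- master_z(master)

  # counts
  counts <- c(up = sum(calls == "up"), down = sum(calls == "down"))
  emit_artifact(em, "de_counts_bar",
                data.frame(category = names(counts), value = unname(counts),
                           fill = names(counts), label = unname(counts),
                           stringsAsFactors = FALSE),
                list(fill_values = deparse_palette(call_colours[c("up", "down")]),
                     x_lab = "", y_lab = "significant genes"))

  tested <- !is.na(lfc)
  sig_col <- ifelse(sig_mask, "significant", "not significant")
  sig_pal <- c("significant" = unname(call_colours["up"]),
               "not significant" = "black")
  mean_test <- master[[paste0("mean.", cmp$test_group)]]
  mean_ref <- master[[paste0("mean.", cmp$reference_group)]]

  # MA
  emit_artifact(em, "de_ma",
                data.frame(x = log10((mean_test + mean_ref)[tested] / 2 + 1),
                           y = lfc[tested], colour = sig_col[tested],
                           stringsAsFactors = FALSE),
                list(colour_values = deparse_palette(sig_pal),
                     x_lab = "log10(mean expression + 1)",
                     y_lab = "log2 fold change",
                     extra_lines = "p <- p + geom_hline(yintercept = 0, linetype = 2, colour = line.colour)"))

  # volcano
  vt <- tested & !is.na(p_raw)
  emit_artifact(em, "de_volcano",
                data.frame(x = lfc[vt],
                           y = -log10(pmax(p_raw[vt], .Machine$double.xmin)),
                           colour = sig_col[vt], stringsAsFactors = FALSE),
                list(colour_values = deparse_palette(sig_pal),
                     x_lab = "log2 fold change", y_lab = "-log10 p",
                     extra_lines = "p <- p + geom_vline(xintercept = 0, linetype = 2, colour = line.colour)"))

  # significant-gene heatmaps over the comparison's samples
  zs <- z[sig_genes, samples, drop = FALSE]
  lims <- symmetric_limits(zs)
  emit_artifact(em, "de_sig_heatmap_clustered",
                heatmap_data(zs, clustered_row_order(zs)),
                list(fill_limits = lims))
  ord_lfc <- sig_genes[order(-lfc[sig_mask])]
  emit_artifact(em, "de_sig_heatmap_unclustered", heatmap_data(zs, ord_lfc),
                list(fill_limits = lims))

  # top-gene violins and tables (ranked by p)
  rank_genes <- function(direction) {
    idx <- which(calls == direction)
    idx[order(p_raw[idx], master$gene_id[idx])]
  }
  stat_cols <- c("symbol", paste0(comparison, c(".log2fc", ".p", ".adj_p")))
  top_table <- function(idx) {
    if (!length(idx)) return(placeholder_table("no significant genes"))
    tt <- master[utils::head(idx, top_n),
                 c(stat_cols, paste0("mean.", grp))]
    names(tt) <- c("symbol", "log2fc", "p", "adj_p", paste("mean", grp))
    tt
  }
  up_idx <- rank_genes("up"); down_idx <- rank_genes("down")
  violin_or_empty <- function(type_id, idx) {
    genes <- master$gene_id[utils::head(idx, min(top_n, 4))]
    dat <- violin_gene_data(master, genes, samples, "expr")
    if (!nrow(dat)) {
      dat <- data.frame(x = grp, y = NA_real_, panel = "no significant genes",
                        stringsAsFactors = FALSE)
    }
    emit_artifact(em, type_id, dat,
                  list(fill_values = deparse_palette(pal),
                       x_lab = "", y_lab = "normalized expression"))
  }
  violin_or_empty("de_top_up_violin", up_idx)
  violin_or_empty("de_top_down_violin", down_idx)

  sig_z <- z[sig_genes, samples, drop = FALSE]
  dat <- if (nrow(sig_z)) {
    data.frame(x = rep(unname(all_groups[samples]), each = nrow(sig_z)),
               y = as.vector(sig_z), panel = "all significant genes",
               stringsAsFactors = FALSE)
  } else data.frame(x = grp, y = NA_real_, panel = "no significant genes",
                    stringsAsFactors = FALSE)
  emit_artifact(em, "de_sig_violin", dat,
                list(fill_values = deparse_palette(pal),
                     x_lab = "", y_lab = "z-score"))

  # spatial analysis
  spatial <- tryCatch(run_spatial(master, comparison, expressed_threshold),
                      rnaevi_error = function(e) NULL)
  spatial_bar <- function(type_id, family) {
    sp <- if (is.null(spatial)) NULL else spatial[spatial$family == family, ]
    dat <- if (is.null(sp) || !nrow(sp)) {
      data.frame(category = character(), value = numeric(),
                 fill = character(), label = character())
    } else {
      data.frame(category = sp$chromosome,
                 value = -log10(pmax(sp$p, .Machine$double.xmin)),
                 fill = "chromosome", label = sp$a, stringsAsFactors = FALSE)
    }
    emit_artifact(em, type_id, dat,
                  list(fill_values = 'c("chromosome" = "grey40")',
                       x_lab = "chromosome", y_lab = "-log10 p"),
                  note = if (is.null(sp) || !nrow(sp))
                    "(no chromosome annotation available)" else NULL)
  }
  spatial_bar("de_spatial_expression", "expression-bias")
  spatial_bar("de_spatial_de", "de-bias")
  spatial_bar("de_spatial_direction", "direction-bias")

  universe <- master$symbol

  # over-representation analysis: all / up / down
  ora <- if (!is.null(gmt_db)) {
    run_ora_directional(master, comparison, gmt_db, universe)
  } else {
    empty <- suppressWarnings(
      run_ora(character(), structure(list(S = "X"), class = "gene_set_db",
                                     descriptions = c(S = "")),
              "X", min_set = 0, max_set = 1))
    list(all = empty[0, ], up = empty[0, ], down = empty[0, ])
  }
  for (d in c("all", "up", "down")) {
    res <- ora[[d]]
    write_tsv_exact(res, file.path(em$out_dir, "data",
                                   sprintf("%s_ora_%s_results.tsv", em$instance, d)))
    emit_artifact(em, sprintf("de_ora_%s_bar", d),
                  top_hits_bar_data(res, top_n, "set_name",
                                    function(t) -log10(pmax(t$p, .Machine$double.xmin)),
                                    function(t) t$k,
                                    function(t) rep("set", nrow(t))),
                  list(fill_values = 'c("set" = "#FB6A4A")',
                       x_lab = "", y_lab = "-log10 p"),
                  note = if (!nrow(res)) "(no gene-set database or no testable set)" else NULL)
    top_set_genes <- if (nrow(res)) strsplit(res$overlap_genes[1], ",")[[1]] else character()
    emit_artifact(em, sprintf("de_ora_%s_box", d),
                  box_symbol_data(master, top_set_genes, samples),
                  list(fill_values = deparse_palette(pal), fill_lab = "group",
                       x_lab = "", y_lab = "z-score"))
    emit_artifact(em, sprintf("de_ora_%s_network", d),
                  network_data(build_shared_gene_network(res, adj_p_cut)),
                  list(size_lab = "significant genes"))
  }
  emit_artifact(em, "de_ora_table",
                if (nrow(ora$all)) utils::head(
                  ora$all[c("set_name", "k", "K", "enrichment_ratio", "p", "adj_p")],
                  2 * top_n)
                else placeholder_table("no over-representation results"))

  # upstream regulator analysis
  ura <- if (!is.null(trrust)) run_ura(master, comparison, trrust, universe)
         else run_ura(master, comparison,
                      data.frame(regulator = character(), target = character(),
                                 mode = character()), universe)
  write_tsv_exact(ura, file.path(em$out_dir, "data",
                                 paste0(em$instance, "_ura_results.tsv")))
  emit_artifact(em, "de_ura_enriched_bar",
                top_hits_bar_data(ura, top_n, "regulator",
                                  function(t) -log10(pmax(t$p, .Machine$double.xmin)),
                                  function(t) t$k,
                                  function(t) rep("regulator", nrow(t))),
                list(fill_values = 'c("regulator" = "#FB6A4A")',
                     x_lab = "", y_lab = "-log10 p"),
                note = if (!nrow(ura)) "(no regulator network supplied)" else NULL)
  zord <- ura[order(-ura$activation_z, ura$regulator), ]
  emit_artifact(em, "de_ura_activated_bar",
                top_hits_bar_data(zord, top_n, "regulator",
                                  function(t) t$activation_z,
                                  function(t) t$k,
                                  function(t) ifelse(t$activation_z > 2,
                                                     "activated", "other")),
                list(fill_values = 'c("activated" = "#B2182B", "other" = "grey60")',
                     x_lab = "", y_lab = "activation z-score",
                     legend_pos = "right", fill_lab = "state"))
  zord2 <- ura[order(ura$activation_z, ura$regulator), ]
  emit_artifact(em, "de_ura_inhibited_bar",
                top_hits_bar_data(zord2, top_n, "regulator",
                                  function(t) t$activation_z,
                                  function(t) t$k,
                                  function(t) ifelse(t$activation_z < -2,
                                                     "inhibited", "other")),
                list(fill_values = 'c("inhibited" = "#2166AC", "other" = "grey60")',
                     x_lab = "", y_lab = "activation z-score",
                     legend_pos = "right", fill_lab = "state"))
  emit_artifact(em, "de_ura_network",
                network_data(build_shared_gene_network(ura, adj_p_cut)),
                list(size_lab = "regulated genes"))
  top_reg_genes <- if (nrow(ura)) strsplit(ura$overlap_genes[1], ",")[[1]] else character()
  emit_artifact(em, "de_ura_box",
                box_symbol_data(master, top_reg_genes, samples),
                list(fill_values = deparse_palette(pal), fill_lab = "group",
                     x_lab = "", y_lab = "z-score"))
  emit_artifact(em, "de_ura_table",
                if (nrow(ura)) utils::head(
                  ura[c("regulator", "K", "k", "n_consistent", "n_inconsistent",
                        "activation_z", "p", "adj_p", "state")], 2 * top_n)
                else placeholder_table("no upstream regulator results"))

  # remaining single-gene views
  rk <- which(tested)
  rk <- rk[order(lfc[rk])]
  emit_artifact(em, "de_fold_rank",
                data.frame(x = seq_along(rk), y = lfc[rk],
                           colour = calls[rk], stringsAsFactors = FALSE),
                list(colour_values = deparse_palette(call_colours),
                     colour_lab = "call", x_lab = "fold-change rank",
                     y_lab = "log2 fold change"))
  emit_artifact(em, "de_p_histogram",
                data.frame(x = p_raw[!is.na(p_raw)]),
                list(bins = "40", x_lab = "p value"))
  emit_artifact(em, "de_mean_scatter",
                data.frame(x = log10(mean_ref + 1), y = log10(mean_test + 1),
                           colour = calls, stringsAsFactors = FALSE),
                list(colour_values = deparse_palette(call_colours),
                     colour_lab = "call",
                     x_lab = sprintf("log10(mean %s + 1)", cmp$reference_group),
                     y_lab = sprintf("log10(mean %s + 1)", cmp$test_group),
                     extra_lines = "p <- p + geom_abline(slope = 1, intercept = 0, linetype = 2, colour = line.colour)"))

  emit_artifact(em, "de_top_up_table", top_table(up_idx))
  emit_artifact(em, "de_top_down_table", top_table(down_idx))
  emit_artifact(em, "de_stats_table", data.frame(
    statistic = c("genes in table", "tested", "upregulated", "downregulated",
                  "not significant", "untested", "adjusted p threshold",
                  "absolute log2fc threshold"),
    value = c(nrow(master), sum(tested), counts["up"], counts["down"],
              sum(calls == "ns"), sum(calls == "untested"),
              cmp$adj_p_threshold, cmp$abs_log2fc_threshold),
    stringsAsFactors = FALSE))

  invisible(finish_instance(em))
}

#' Run the multiple differential expression (MDE) workflow
#'
#' Cross-comparison analysis of two or more differential comparisons:
#' per-comparison counts, union significant-gene heatmaps, pairwise overlap
#' (Venn) statistics, fold-versus-fold scatter plots, and differential
#' expression signature analysis (profile binning + meta-gene merging) with
#' per-signature heatmap, meta-gene violin and ORA top hits.
#'
#' @param master A master gene table.
#' @param comparisons Character vector of >= 2 comparison names.
#' @param out_dir Workflow instance output directory.
#' @param gmt_db Optional `gene_set_db` for per-signature ORA.
#' @param scc_threshold Spearman threshold for signature merging (default 0.9).
#' @param max_signatures Cap on per-signature plot artifacts (default 6).
#' @inheritParams run_de
#' @return List of artifact records (invisibly).
#' @export
run_mde <- function(master, comparisons, out_dir, gmt_db = NULL,
                    scc_threshold = 0.9, top_n = 5, max_signatures = 6,
                    bin = snippet_bin(), dpi = 300, formats = c("png", "svg"),
                    execute = TRUE) {
  if (length(comparisons) < 2) evi_abort("MDE needs >= 2 comparisons")
  cmp_meta <- master_comparisons(master)[comparisons]
  if (any(vapply(cmp_meta, is.null, logical(1)))) {
    evi_abort("unknown comparison among: %s", paste(comparisons, collapse = ", "))
  }
  em <- new_emitter(out_dir, bin, dpi, formats, execute)
  all_groups <- master_groups(master)
  grp <- unique(unlist(lapply(cmp_meta, function(x)
    c(x$reference_group, x$test_group))))
  grp <- master_group_order(master)[master_group_order(master) %in% grp]
  samples <- master_samples(master)[all_groups %in% grp]
  pal <- group_palette(grp)
  z <- master_z(master)

  calls <- sapply(comparisons, function(cc) master_calls(master, cc))
  counts <- do.call(rbind, lapply(comparisons, function(cc) {
    cl <- master_calls(master, cc)
    data.frame(category = cc, value = c(sum(cl == "up"), sum(cl == "down")),
               fill = c("up", "down"),
               label = c(sum(cl == "up"), sum(cl == "down")),
               stringsAsFactors = FALSE)
  }))
  emit_artifact(em, "mde_counts_bar", counts,
                list(fill_values = deparse_palette(call_colours[c("up", "down")]),
                     fill_lab = "direction", legend_pos = "right",
                     x_lab = "", y_lab = "significant genes"))

  union_mask <- rowSums(calls == "up" | calls == "down") > 0
  union_genes <- master$gene_id[union_mask]
  zu <- z[union_genes, samples, drop = FALSE]
  lims <- symmetric_limits(zu)
  emit_artifact(em, "mde_union_heatmap_clustered",
                heatmap_data(zu, clustered_row_order(zu)),
                list(fill_limits = lims))
  emit_artifact(em, "mde_union_heatmap_unclustered", heatmap_data(zu),
                list(fill_limits = lims))

  # pairwise overlap (Venn statistics)
  pairs <- utils::combn(comparisons, 2, simplify = FALSE)
  overlap_rows <- list()
  overlap_bar <- list()
  for (pr in pairs) {
    tested_both <- !is.na(master[[paste0(pr[1], ".log2fc")]]) &
      !is.na(master[[paste0(pr[2], ".log2fc")]])
    uni <- master$symbol[tested_both]
    a <- significant_symbols(master, pr[1])
    b <- significant_symbols(master, pr[2])
    ov <- run_overlap(a, b, uni)
    overlap_rows[[length(overlap_rows) + 1]] <-
      cbind(data.frame(pair = paste(pr, collapse = " / ")), ov)
    lab <- paste(pr, collapse = "/")
    overlap_bar[[length(overlap_bar) + 1]] <- data.frame(
      category = lab,
      value = c(ov$n_a - ov$overlap, ov$overlap, ov$n_b - ov$overlap),
      fill = c("first only", "shared", "second only"),
      label = c(ov$n_a - ov$overlap, ov$overlap, ov$n_b - ov$overlap),
      stringsAsFactors = FALSE)
  }
  overlap_tab <- do.call(rbind, overlap_rows)
  overlap_tab$adj_p <- bh_adjust(overlap_tab$p)
  emit_artifact(em, "mde_overlap_table", overlap_tab)
  emit_artifact(em, "mde_overlap_bar", do.call(rbind, overlap_bar),
                list(fill_values = 'c("first only" = "#74ADD1", "shared" = "#B2182B", "second only" = "#4575B4")',
                     fill_lab = "part", legend_pos = "right",
                     x_lab = "", y_lab = "genes"))

  # fold versus fold, one artifact per comparison pair
  ff_pal <- c(both = "#B2182B", `first only` = "#33A02C",
              `second only` = "#2166AC", neither = "black")
  for (pr in pairs) {
    l1 <- master[[paste0(pr[1], ".log2fc")]]
    l2 <- master[[paste0(pr[2], ".log2fc")]]
    keep <- !is.na(l1) & !is.na(l2)
    s1 <- master_calls(master, pr[1])[keep] %in% c("up", "down")
    s2 <- master_calls(master, pr[2])[keep] %in% c("up", "down")
    cat4 <- ifelse(s1 & s2, "both",
                   ifelse(s1, "first only",
                          ifelse(s2, "second only", "neither")))
    scc <- if (sum(keep) >= 3) spearman(l1[keep], l2[keep]) else NA_real_
    emit_artifact(em, "mde_fold_fold",
                  data.frame(x = l2[keep], y = l1[keep], colour = cat4,
                             stringsAsFactors = FALSE),
                  list(colour_values = deparse_palette(ff_pal),
                       colour_lab = "significant in",
                       subtitle = if (is.na(scc)) "" else sprintf("SCC = %.2f", scc),
                       x_lab = paste("log2 fold change:", pr[2]),
                       y_lab = paste("log2 fold change:", pr[1]),
                       extra_lines = "p <- p + geom_hline(yintercept = 0, linetype = 2, colour = line.colour) + geom_vline(xintercept = 0, linetype = 2, colour = line.colour)"),
                  sub = paste(pr, collapse = "_"))
  }

  # differential expression signatures
  bins <- bin_profiles(master, comparisons)
  sigs <- merge_signatures(bins, master, scc_threshold)
  assign_tab <- signature_assignments(sigs)
  write_tsv_exact(assign_tab, file.path(em$out_dir, "data",
                                        paste0(em$instance, "_signatures.tsv")))
  write_tsv_exact(signature_metagenes(sigs),
                  file.path(em$out_dir, "data",
                            paste0(em$instance, "_signature_metagenes.tsv")))
  write_tsv_exact(sigs$merge_log,
                  file.path(em$out_dir, "data",
                            paste0(em$instance, "_signature_merge_log.tsv")))

  shown <- utils::head(sigs$signatures, max_signatures)
  if (!length(shown)) {
    emit_artifact(em, "mde_signature_heatmap",
                  heatmap_data(zu[0, , drop = FALSE]),
                  list(fill_limits = "c(-1, 1)"), sub = "1",
                  note = "(no signatures: no significant genes)")
    emit_artifact(em, "mde_signature_violin",
                  data.frame(x = grp, y = NA_real_, panel = "no signatures",
                             stringsAsFactors = FALSE),
                  list(fill_values = deparse_palette(pal),
                       x_lab = "", y_lab = "meta-gene z-score"), sub = "1")
    emit_artifact(em, "mde_signature_ora_bar",
                  top_hits_bar_data(data.frame(), top_n, "set_name",
                                    identity, identity, identity),
                  list(fill_values = 'c("set" = "#FB6A4A")',
                       x_lab = "", y_lab = "-log10 p"), sub = "1",
                  note = "(no signatures)")
  }
  for (s in shown) {
    zsig <- z[s$genes, samples, drop = FALSE]
    emit_artifact(em, "mde_signature_heatmap",
                  heatmap_data(zsig, clustered_row_order(zsig)),
                  list(fill_limits = symmetric_limits(zsig)),
                  sub = as.character(s$id))
    emit_artifact(em, "mde_signature_violin",
                  data.frame(x = unname(all_groups[samples]),
                             y = unname(s$meta_gene[samples]),
                             panel = sprintf("signature %d (%d genes)",
                                             s$id, length(s$genes)),
                             stringsAsFactors = FALSE),
                  list(fill_values = deparse_palette(pal),
                       x_lab = "", y_lab = "meta-gene z-score"),
                  sub = as.character(s$id))
    res <- if (!is.null(gmt_db)) {
      sym <- master$symbol[match(s$genes, master$gene_id)]
      suppressWarnings(run_ora(sym, gmt_db, master$symbol))
    } else data.frame()
    emit_artifact(em, "mde_signature_ora_bar",
                  top_hits_bar_data(res, top_n, "set_name",
                                    function(t) -log10(pmax(t$p, .Machine$double.xmin)),
                                    function(t) t$k,
                                    function(t) rep("set", nrow(t))),
                  list(fill_values = 'c("set" = "#FB6A4A")',
                       x_lab = "", y_lab = "-log10 p"),
                  sub = as.character(s$id),
                  note = if (!nrow(res)) "(no gene-set database supplied)" else NULL)
  }

  invisible(finish_instance(em))
}
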