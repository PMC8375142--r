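# Single-command orchestration: validate inputs, build the master gene
# table, run every configured workflow instance, and write the combined
# scripts, reports, manifest and log.

#' Build a pipeline run configuration
#'
#' @param sample_sheet,em,background Paths to the sample sheet, expression
#'   matrix and genome background files (`background` optional).
#' @param de_tables Named list of DE table paths (names are referenced by
#'   `comparisons`).
#' @param comparisons List of lists: `name`, `test`, `ref`, `de` (a name in
#'   `de_tables`), optional `adj_p_threshold`, `abs_log2fc_threshold`.
#' @param workflows List of lists: `kind` ("NE", "DE" or "MDE") plus, for
#'   DE, `comparison`; for MDE, `comparisons` (>= 2 names); for NE, optional
#'   `groups`. Any number of instances of any kind may be declared.
#' @param gmt,trrust Optional paths to a GMT gene-set database and a
#'   TRRUST-format regulator network.
#' @param group_order Optional explicit group ordering for all plots.
#' @param adj_p_threshold,abs_log2fc_threshold Default significance
#'   thresholds applied to comparisons that do not override them.
#' @param scc_threshold Signature-merging Spearman threshold (default 0.9).
#' @param top_n Top hits in tables and bars (default 5).
#' @param expressed_threshold Spatial-analysis expression cut-off (default 1).
#' @param dpi,formats Image resolution (default 300) and formats
#'   (default png + svg).
#' @param seed Integer seed fixing all randomness of the run (default 1).
#' @param snippet_dir Optional replacement snippet bin directory.
#' @return A `run_config` list.
#' @export
run_config <- function(sample_sheet, em, background = NULL,
                       de_tables = list(), comparisons = list(),
                       workflows = list(), gmt = NULL, trrust = NULL,
                       group_order = NULL, adj_p_threshold = 0.05,
                       abs_log2fc_threshold = 1, scc_threshold = 0.9,
                       top_n = 5, expressed_threshold = 1, dpi = 300,
                       formats = c("png", "svg"), seed = 1,
                       snippet_dir = NULL) {
  structure(
    list(sample_sheet = sample_sheet, em = em, background = background,
         de_tables = de_tables, comparisons = comparisons,
         workflows = workflows, gmt = gmt, trrust = trrust,
         group_order = group_order, adj_p_threshold = adj_p_threshold,
         abs_log2fc_threshold = abs_log2fc_threshold,
         scc_threshold = scc_threshold, top_n = top_n,
         expressed_threshold = expressed_threshold, dpi = dpi,
         formats = formats, seed = as.integer(seed),
         snippet_dir = snippet_dir),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of [run_config()];
#'   relative input paths are resolved against the YAML file's directory.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) evi_abort("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(file.exists(p), p, file.path(base, p))
  }
  y$sample_sheet <- resolve(y$sample_sheet)
  y$em <- resolve(y$em)
  y$background <- resolve(y$background)
  y$gmt <- resolve(y$gmt)
  y$trrust <- resolve(y$trrust)
  y$de_tables <- lapply(y$de_tables, resolve)
  do.call(run_config, y)
}

validate_run_config <- function(config) {
  errs <- character()
  need <- function(cond, msg, ...) {
    if (!cond) errs <<- c(errs, sprintf(msg, ...))
  }
  need(!is.null(config$sample_sheet) && file.exists(config$sample_sheet %||% ""),
       "sample sheet missing: %s", config$sample_sheet %||% "<unset>")
  need(!is.null(config$em) && file.exists(config$em %||% ""),
       "expression matrix missing: %s", config$em %||% "<unset>")
  if (!is.null(config$background)) {
    need(file.exists(config$background), "background file missing: %s",
         config$background)
  }
  for (nm in names(config$de_tables)) {
    need(file.exists(config$de_tables[[nm]]),
         "DE table '%s' missing: %s", nm, config$de_tables[[nm]])
  }
  if (!is.null(config$gmt)) {
    need(file.exists(config$gmt), "GMT file missing: %s", config$gmt)
  }
  if (!is.null(config$trrust)) {
    need(file.exists(config$trrust), "regulator network missing: %s",
         config$trrust)
  }
  cmp_names <- vapply(config$comparisons, function(x) x$name %||% "",
                      character(1))
  for (cmp in config$comparisons) {
    need(!is.null(cmp$name) && nzchar(cmp$name), "comparison without a name")
    need((cmp$de %||% "") %in% names(config$de_tables),
         "comparison '%s': unknown DE table '%s'", cmp$name %||% "?",
         cmp$de %||% "<unset>")
  }
  need(length(config$workflows) > 0, "no workflow instances declared")
  for (wf in config$workflows) {
    kind <- wf$kind %||% "<unset>"
    need(kind %in% c("NE", "DE", "MDE"), "unknown workflow kind '%s'", kind)
    if (identical(kind, "DE")) {
      need((wf$comparison %||% "") %in% cmp_names,
           "DE workflow references unknown comparison '%s'",
           wf$comparison %||% "<unset>")
    }
    if (identical(kind, "MDE")) {
      cc <- wf$comparisons %||% character()
      need(length(cc) >= 2, "MDE workflow needs >= 2 comparisons")
      need(all(cc %in% cmp_names),
           "MDE workflow references unknown comparison(s): %s",
           paste(setdiff(cc, cmp_names), collapse = ", "))
    }
  }
  errs
}

#' Run the whole pipeline
#'
#' Executes the run as a single command: validates the inputs (collecting
#' every problem before failing), assembles the master gene table, runs each
#' declared workflow instance (emitting statistics files, per-plot data,
#' standalone and combined scripts, and images), renders one HTML report per
#' instance plus an index, and writes a machine-readable manifest.
#'
#' @param config A [run_config()] (or path to a YAML config).
#' @param output_dir Output root (created; must be empty or absent unless
#'   `overwrite`).
#' @param overwrite Allow writing into an existing non-empty directory.
#' @param execute Render images (default TRUE; FALSE still writes data and
#'   scripts).
#' @return Invisibly, a list with `master`, `instances`, `artifacts` and
#'   `manifest_path`.
#' @export
run_pipeline <- function(config, output_dir, overwrite = FALSE,
                         execute = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  errs <- validate_run_config(config)
  if (length(errs)) {
    evi_abort("input validation failed:\n  - %s",
              paste(errs, collapse = "\n  - "))
  }
  if (dir.exists(output_dir) && length(list.files(output_dir)) && !overwrite) {
    evi_abort("output directory '%s' is not empty (set overwrite = TRUE)",
              output_dir)
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  log_lines <- c("run started", sprintf("seed: %d", config$seed))
  logmsg <- function(msg, ...) log_lines <<- c(log_lines, sprintf(msg, ...))

  # ingest
  sheet <- read_sample_sheet(config$sample_sheet)
  if (!is.null(config$group_order)) {
    sheet <- sample_sheet(sheet$samples$sample_id, sheet$samples$group,
                          group_order = config$group_order)
  }
  emx <- read_expression_matrix(config$em)
  background <- if (!is.null(config$background)) read_background(config$background)
  de_tabs <- lapply(config$de_tables, read_differential_table)
  comparisons <- lapply(config$comparisons, function(cmp) {
    comparison_spec(
      cmp$name, cmp$test, cmp$ref, de_tabs[[cmp$de]],
      adj_p_threshold = cmp$adj_p_threshold %||% config$adj_p_threshold,
      abs_log2fc_threshold = cmp$abs_log2fc_threshold %||% config$abs_log2fc_threshold
    )
  })
  gmt_db <- if (!is.null(config$gmt)) read_gmt(config$gmt)
  trrust <- if (!is.null(config$trrust)) read_trrust(config$trrust)
  logmsg("inputs validated: %d samples, %d genes, %d comparison(s)",
         nrow(sheet$samples), nrow(emx), length(comparisons))

  master <- build_master_table(sheet, emx, comparisons, background)
  write_master_table(master, file.path(output_dir, "master_gene_table.tsv"))
  logmsg("master gene table written (%d genes)", nrow(master))

  bin <- snippet_bin(config$snippet_dir %||%
                       system.file("snippets", package = "rnaevi"))

  kind_count <- c(NE = 0L, DE = 0L, MDE = 0L)
  instances <- list()
  all_artifacts <- list()
  for (wf in config$workflows) {
    kind <- wf$kind
    kind_count[kind] <- kind_count[kind] + 1L
    inst_id <- paste0(tolower(kind), kind_count[kind])
    inst_dir <- file.path(output_dir, inst_id)
    arts <- switch(kind,
      NE = run_ne(master, inst_dir, groups = wf$groups,
                  top_n = config$top_n, bin = bin, dpi = config$dpi,
                  formats = config$formats, execute = execute),
      DE = run_de(master, wf$comparison, inst_dir, gmt_db = gmt_db,
                  trrust = trrust, top_n = config$top_n,
                  expressed_threshold = config$expressed_threshold,
                  bin = bin, dpi = config$dpi, formats = config$formats,
                  execute = execute),
      MDE = run_mde(master, wf$comparisons, inst_dir, gmt_db = gmt_db,
                    scc_threshold = wf$scc_threshold %||% config$scc_threshold,
                    top_n = config$top_n, bin = bin, dpi = config$dpi,
                    formats = config$formats, execute = execute)
    )
    render_report(arts, inst_dir, title = sprintf("%s workflow: %s", kind, inst_id))
    instances[[inst_id]] <- list(id = inst_id, kind = kind,
                                 n_artifacts = length(arts))
    all_artifacts <- c(all_artifacts, arts)
    logmsg("workflow %s (%s): %d plot artifacts", inst_id, kind, length(arts))
  }
  render_index(instances, output_dir)

  manifest <- list(
    package = "rnaevi",
    seed = config$seed,
    parameters = list(
      adj_p_threshold = config$adj_p_threshold,
      abs_log2fc_threshold = config$abs_log2fc_threshold,
      scc_threshold = config$scc_threshold,
      top_n = config$top_n,
      expressed_threshold = config$expressed_threshold,
      dpi = config$dpi, formats = config$formats
    ),
    inputs = list(
      sample_sheet = basename(config$sample_sheet),
      em = basename(config$em),
      background = if (!is.null(config$background)) basename(config$background),
      de_tables = lapply(config$de_tables, basename),
      gmt = if (!is.null(config$gmt)) basename(config$gmt),
      trrust = if (!is.null(config$trrust)) basename(config$trrust)
    ),
    plot_type_counts = as.list(registry_counts(
      vapply(all_artifacts, `[[`, character(1), "type_id"))),
    instances = unname(instances),
    artifacts = lapply(unname(all_artifacts), function(a) {
      a[c("id", "type_id", "workflow", "instance", "data_file",
          "script_file", "images", "title")]
    })
  )
  manifest_path <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  logmsg("manifest written: %d artifacts", length(all_artifacts))
  writeLines(log_lines, file.path(output_dir, "run.log"))

  invisible(list(master = master, instances = instances,
                 artifacts = all_artifacts, manifest_path = manifest_path))
}
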