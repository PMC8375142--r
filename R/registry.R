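# The versioned plot-type registry: the fixed catalogue of visualisation
# types the three workflows emit, with per-category counts pinned by tests
# (quality control 1, expression 7, differential expression 33, multiple
# differential expression 9; 50 in total). Counting rules: parameter-only
# variants (e.g. labelled vs unlabelled) are one type; clustered and
# unclustered heatmaps of the same data are one type each; ORA visual types
# are counted once regardless of the database used.

#' The plot-type registry
#'
#' @return data.frame with one row per plot type: `type_id`, `workflow`
#'   (NE/DE/MDE), `category` (qc/expression/differential/multiple),
#'   `family` (snippet family), default `width`/`height`, `flip`, `title`,
#'   `description`, `legend`, `methods`.
#' @export
plot_registry <- function() {
  path <- system.file("registry", "plot_types.tsv", package = "rnaevi")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Plot-type counts per category
#'
#' @param types Character vector of plot type ids (defaults to the whole
#'   registry); duplicates are counted once.
#' @return Named integer vector: qc, expression, differential, multiple,
#'   total.
#' @export
registry_counts <- function(types = NULL) {
  reg <- plot_registry()
  if (!is.null(types)) reg <- reg[reg$type_id %in% unique(types), , drop = FALSE]
  out <- c(
    qc = sum(reg$category == "qc"),
    expression = sum(reg$category == "expression"),
    differential = sum(reg$category == "differential"),
    multiple = sum(reg$category == "multiple")
  )
  c(out, total = sum(out))
}
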