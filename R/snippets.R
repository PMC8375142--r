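# The script-composition engine. Every emitted plot script is assembled from
# a central bin of small code snippets: a master config lists the analysis
# steps of each workflow kind, a per-step config lists the snippets of that
# step in order, and snippets carry {{tag}} placeholders that are substituted
# at composition time. Editing one shared snippet (e.g. the theme) therefore
# restyles every script that uses it.

# snippets present in every script exactly once (also reused by the combined
# per-workflow script, where they appear once at the top)
SHARED_SNIPPETS <- c("header", "params", "theme", "save_function")

#' Load the snippet bin
#'
#' Reads the snippet fragments, the master config (ordered analysis steps
#' per workflow kind) and the per-step configs (ordered snippet names per
#' step). A user-supplied directory with the same layout can replace the
#' shipped bin to change the default look of every plot.
#'
#' @param dir Directory containing `snippets/`, `steps/` and
#'   `master_config.tsv`; defaults to the bin shipped with the package.
#' @return A `snippet_bin` list: `snippets` (named character), `steps`
#'   (named list of snippet-name vectors), `master` (data.frame
#'   workflow/type_id).
#' @export
snippet_bin <- function(dir = system.file("snippets", package = "rnaevi")) {
  if (!dir.exists(dir)) evi_abort("snippet directory not found: %s", dir)
  files <- list.files(file.path(dir, "snippets"), pattern = "\\.snippet$",
                      full.names = TRUE)
  snippets <- stats::setNames(
    vapply(files, function(f) paste(readLines(f, warn = FALSE), collapse = "\n"),
           character(1)),
    sub("\\.snippet$", "", basename(files))
  )
  step_files <- list.files(file.path(dir, "steps"), pattern = "\\.config$",
                           full.names = TRUE)
  steps <- stats::setNames(
    lapply(step_files, function(f) readLines(f, warn = FALSE)),
    sub("\\.config$", "", basename(step_files))
  )
  master <- utils::read.delim(file.path(dir, "master_config.tsv"),
                              stringsAsFactors = FALSE)
  for (st in names(steps)) {
    missing <- setdiff(steps[[st]], names(snippets))
    if (length(missing)) {
      evi_abort("step '%s' references unknown snippet(s): %s", st,
                paste(missing, collapse = ", "))
    }
  }
  structure(list(snippets = snippets, steps = steps, master = master),
            class = "snippet_bin")
}

substitute_tags <- function(text, context, step) {
  for (nm in names(context)) {
    text <- gsub(paste0("{{", nm, "}}"), as.character(context[[nm]]),
                 text, fixed = TRUE)
  }
  left <- unique(unlist(regmatches(text, gregexpr("\\{\\{[a-zA-Z0-9_]+\\}\\}", text))))
  if (length(left)) {
    evi_abort("unresolved tag(s) %s in step '%s'", paste(left, collapse = ", "), step)
  }
  text
}

#' Compose a standalone plot script
#'
#' Concatenates the snippets configured for one analysis step, in order,
#' substituting every `{{tag}}` placeholder from `context`. An unresolved
#' tag is a build error naming the tag and the step.
#'
#' @param step Step id (a plot type id from the registry).
#' @param bin A [snippet_bin()].
#' @param context Named list of tag values.
#' @return The script text (single string).
#' @export
compose_script <- function(step, bin, context) {
  if (!step %in% names(bin$steps)) evi_abort("unknown step '%s'", step)
  text <- paste(unname(bin$snippets[bin$steps[[step]]]), collapse = "\n")
  substitute_tags(text, context, step)
}

#' Compose the combined per-workflow script
#'
#' One script that regenerates every plot of a workflow instance. The shared
#' snippets (header, visual parameters, theme, save function) appear once at
#' the top, so e.g. the font of all plots can be changed by editing a single
#' parameter; each plot then contributes its data-loading, plotting and
#' saving sections.
#'
#' @param artifacts List of artifact records (each with `type_id` and
#'   `context` as used for its per-plot script).
#' @param bin A [snippet_bin()].
#' @param shared_context Tag values for the shared snippets.
#' @return The combined script text.
#' @export
compose_workflow_script <- function(artifacts, bin, shared_context) {
  if (!length(artifacts)) evi_abort("no artifacts to combine")
  first_step <- artifacts[[1]]$type_id
  shared <- intersect(bin$steps[[first_step]], SHARED_SNIPPETS)
  out <- substitute_tags(
    paste(unname(bin$snippets[shared]), collapse = "\n"),
    shared_context, "combined:shared"
  )
  for (a in artifacts) {
    part <- setdiff(bin$steps[[a$type_id]], SHARED_SNIPPETS)
    section <- paste0("\n\n", strrep("#", 72), "\n## ", a$id, "\n",
                      paste(unname(bin$snippets[part]), collapse = "\n"))
    out <- paste0(out, substitute_tags(section, a$context, a$type_id))
  }
  out
}

# Execute a composed script file in a fresh environment with the working
# directory set to the script's directory (the path convention the scripts
# are written for). Used by the pipeline to render each image.
run_plot_script <- function(path) {
  old <- setwd(dirname(path))
  on.exit(setwd(old), add = TRUE)
  env <- new.env(parent = globalenv())
  suppressMessages(sys.source(basename(path), envir = env))
  invisible(TRUE)
}
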