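# Self-contained HTML reports: one per workflow instance plus a run index.
# Every plot appears with its description, figure legend, methods and the
# generating R code inside collapsible drop-downs, and a hyperlinked
# contents sidebar links to each analysis step.

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

embed_image <- function(path) {
  if (!file.exists(path)) return("<p class='missing'>image not rendered</p>")
  raw <- readBin(path, "raw", file.info(path)$size)
  sprintf("<img src='data:image/png;base64,%s' alt='%s'/>",
          jsonlite::base64_enc(raw), html_escape(basename(path)))
}

report_css <- "
body { font-family: sans-serif; margin: 0; color: #222; }
#sidebar { position: fixed; top: 0; left: 0; bottom: 0; width: 260px;
  overflow-y: auto; background: #f4f4f4; padding: 14px;
  border-right: 1px solid #ddd; }
#sidebar a { display: block; text-decoration: none; color: #2166AC;
  padding: 2px 0; font-size: 13px; }
#content { margin-left: 290px; padding: 18px; max-width: 900px; }
.artifact { border-bottom: 1px solid #eee; padding: 12px 0; }
.artifact img { max-width: 100%; border: 1px solid #eee; }
details { margin: 4px 0; }
summary { cursor: pointer; color: #444; font-weight: bold; font-size: 13px; }
pre { background: #f8f8f8; padding: 8px; overflow-x: auto; font-size: 12px; }
h1 { font-size: 22px; } h2 { font-size: 17px; margin-bottom: 2px; }
.missing { color: #B2182B; font-style: italic; }
.empty-note { color: #666; font-style: italic; }
"

#' Render the HTML report for one workflow instance
#'
#' A single self-contained HTML file (images embedded as data URIs) with a
#' hyperlinked contents sidebar and, per plot, the description, figure
#' legend, methods and generating R code hidden in drop-down menus.
#'
#' @param artifacts Artifact list as returned by [run_ne()], [run_de()] or
#'   [run_mde()].
#' @param out_dir The instance output directory (report written as
#'   `report.html` inside it).
#' @param title Report title.
#' @return Path of the written report, invisibly.
#' @export
render_report <- function(artifacts, out_dir, title = basename(out_dir)) {
  sidebar <- character()
  body <- character()
  for (a in artifacts) {
    anchor <- a$id
    sidebar <- c(sidebar, sprintf("<a href='#%s'>%s</a>", anchor,
                                  html_escape(a$title)))
    script_path <- file.path(out_dir, a$script_file)
    code <- if (file.exists(script_path)) {
      paste(readLines(script_path, warn = FALSE), collapse = "\n")
    } else ""
    png <- file.path(out_dir, a$images[grepl("\\.png$", a$images)][1])
    empty_note <- if (grepl("\\(", a$description)) {
      sprintf("<p class='empty-note'>%s</p>",
              html_escape(sub("^[^(]*", "", a$description)))
    } else ""
    body <- c(body, sprintf(
      "<div class='artifact' id='%s'>
<h2>%s</h2>
%s
%s
<details><summary>Description</summary><p>%s</p></details>
<details><summary>Figure legend</summary><p>%s</p></details>
<details><summary>Methods</summary><p>%s</p></details>
<details><summary>R code</summary><pre>%s</pre></details>
<p><small>data: %s &middot; script: %s</small></p>
</div>",
      anchor, html_escape(a$title), embed_image(png), empty_note,
      html_escape(a$description), html_escape(a$legend),
      html_escape(a$methods), html_escape(code),
      html_escape(a$data_file), html_escape(a$script_file)))
  }
  html <- sprintf(
    "<!DOCTYPE html><html><head><meta charset='utf-8'/><title>%s</title>
<style>%s</style></head><body>
<div id='sidebar'><h1>%s</h1>%s</div>
<div id='content'>%s</div>
</body></html>",
    html_escape(title), report_css, html_escape(title),
    paste(sidebar, collapse = "\n"), paste(body, collapse = "\n"))
  path <- file.path(out_dir, "report.html")
  writeLines(html, path)
  invisible(path)
}

render_index <- function(instances, output_dir, title = "run report") {
  items <- vapply(instances, function(x) {
    sprintf("<li><a href='%s/report.html'>%s</a> (%s, %d plots)</li>",
            x$id, x$id, x$kind, x$n_artifacts)
  }, character(1))
  html <- sprintf(
    "<!DOCTYPE html><html><head><meta charset='utf-8'/><title>%s</title>
<style>body { font-family: sans-serif; margin: 30px; }</style></head>
<body><h1>%s</h1><ul>%s</ul></body></html>",
    html_escape(title), html_escape(title), paste(items, collapse = "\n"))
  path <- file.path(output_dir, "index.html")
  writeLines(html, path)
  invisible(path)
}
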