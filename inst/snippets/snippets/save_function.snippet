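
# --- image writer: one file per requested format ---
save_plot <- function(p, path_base, width, height) {
  for (fmt in image.formats) {
    file <- paste0(path_base, ".", fmt)
    if (fmt == "svg") {
      ggsave(file, p, width = width, height = height, device = grDevices::svg)
    } else {
      ggsave(file, p, width = width, height = height, dpi = plot.dpi)
    }
  }
  invisible(path_base)
}
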