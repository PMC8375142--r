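
# --- default theme shared by all plots ---
evi_theme <- function() {
  theme_bw(base_size = font.size, base_family = font.family) +
    theme(panel.grid.minor = element_blank(),
          strip.background = element_blank(),
          strip.text = element_text(face = "bold"),
          plot.title = element_text(face = "bold"),
          legend.key.size = unit(0.9, "lines"))
}
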