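
# --- shared-genes network (precomputed circular layout) ---
nodes <- dat[dat$element == "node", , drop = FALSE]
edges <- dat[dat$element == "edge", , drop = FALSE]
p <- ggplot() +
  geom_segment(data = edges, aes(x = x, y = y, xend = xend, yend = yend),
               colour = line.colour, linewidth = 0.4) +
  geom_point(data = nodes, aes(x, y, size = size, colour = intensity)) +
  geom_text(data = nodes, aes(x, y, label = label), vjust = -1.4,
            size = font.size / 3, family = font.family) +
  scale_colour_gradient(low = "mistyrose", high = sig.colour,
                        name = "-log10 p") +
  scale_size_continuous(name = "{{size_lab}}", range = c(2, 8)) +
  expand_limits(x = c(-1.45, 1.45), y = c(-1.35, 1.35)) +
  labs(title = "{{title}}") +
  theme_void(base_size = font.size) +
  theme(plot.title = element_text(face = "bold"))
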