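
# --- heatmap (tile) with symmetric diverging colours ---
dat$row <- factor(dat$row, levels = rev(unique(dat$row)))
dat$col <- factor(dat$col, levels = unique(dat$col))
p <- ggplot(dat, aes(col, row, fill = value)) +
  geom_tile() +
  scale_fill_gradient2(low = heat.low, mid = heat.mid, high = heat.high,
                       limits = {{fill_limits}}, name = "{{fill_lab}}") +
  labs(title = "{{title}}", x = "", y = "") +
  evi_theme() +
  theme(axis.text.y = {{row_text}},
        axis.text.x = element_text(angle = 60, hjust = 1),
        axis.ticks.y = element_blank(),
        panel.grid = element_blank())
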