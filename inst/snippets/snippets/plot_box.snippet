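
# --- boxplots ---
dat$x <- factor(dat$x, levels = unique(dat$x))
dat$fill <- factor(dat$fill, levels = unique(dat$fill))
p <- ggplot(dat, aes(x, y, fill = fill)) +
  geom_boxplot(outlier.size = 0.5, linewidth = 0.3) +
  scale_fill_manual(values = {{fill_values}}, name = "{{fill_lab}}") +
  labs(title = "{{title}}", x = "{{x_lab}}", y = "{{y_lab}}") +
  evi_theme() +
  theme(axis.text.x = element_text(angle = 60, hjust = 1))
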