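
# --- scatter plot ---
dat$colour <- factor(dat$colour, levels = unique(dat$colour))
p <- ggplot(dat, aes(x, y, colour = colour)) +
  geom_point(size = point.size, alpha = 0.8) +
  scale_colour_manual(values = {{colour_values}}, name = "{{colour_lab}}",
                      drop = FALSE) +
  labs(title = "{{title}}", subtitle = "{{subtitle}}",
       x = "{{x_lab}}", y = "{{y_lab}}") +
  evi_theme() +
  theme(legend.position = "{{legend_pos}}")
{{extra_lines}}
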