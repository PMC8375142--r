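
# --- per-sample density curves ---
p <- ggplot(dat, aes(x, colour = group)) +
  geom_density(linewidth = 0.5) +
  scale_colour_manual(values = {{colour_values}}, name = "{{colour_lab}}") +
  labs(title = "{{title}}", x = "{{x_lab}}", y = "density") +
  evi_theme()
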