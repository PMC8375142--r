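
# --- histogram ---
p <- ggplot(dat, aes(x)) +
  geom_histogram(bins = {{bins}}, fill = "grey70", colour = line.colour,
                 linewidth = 0.2, boundary = 0) +
  labs(title = "{{title}}", x = "{{x_lab}}", y = "count") +
  evi_theme()
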