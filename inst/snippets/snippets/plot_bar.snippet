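
# --- bar chart with data labels ---
dat$category <- factor(dat$category, levels = unique(dat$category))
dat$fill <- factor(dat$fill, levels = unique(dat$fill))
p <- ggplot(dat, aes(category, value, fill = fill)) +
  geom_col(position = position_dodge2(preserve = "single"),
           colour = line.colour, linewidth = 0.2) +
  geom_text(aes(label = label),
            position = position_dodge2(width = 0.9, preserve = "single"),
            vjust = -0.4, size = font.size / 3.2) +
  scale_fill_manual(values = {{fill_values}}, name = "{{fill_lab}}") +
  scale_y_continuous(expand = expansion(mult = c(0.02, 0.12))) +
  labs(title = "{{title}}", x = "{{x_lab}}", y = "{{y_lab}}") +
  evi_theme() +
  theme(legend.position = "{{legend_pos}}",
        axis.text.x = element_text(angle = 45, hjust = 1))
{{flip_line}}
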