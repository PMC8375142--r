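
# --- violin + jitter with mean and standard-deviation overlay ---
dat$x <- factor(dat$x, levels = unique(dat$x))
dat$panel <- factor(dat$panel, levels = unique(dat$panel))
p <- ggplot(dat, aes(x, y)) +
  geom_violin(aes(fill = x), colour = line.colour, alpha = 0.8,
              linewidth = 0.3, scale = "width") +
  geom_jitter(width = jitter.width, size = point.size, colour = "black") +
  stat_summary(fun.data = function(v) {
    data.frame(y = mean(v), ymin = mean(v) - sd(v), ymax = mean(v) + sd(v))
  }, geom = "errorbar", colour = mean.colour, width = 0.15, linewidth = 0.5) +
  stat_summary(fun = mean, geom = "point", colour = mean.colour, size = 1.8) +
  facet_wrap(~panel, scales = "free_y") +
  scale_fill_manual(values = {{fill_values}}, guide = "none") +
  labs(title = "{{title}}", x = "{{x_lab}}", y = "{{y_lab}}") +
  evi_theme()
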