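
# --- table rendered as an image; the data file is the table itself ---
tab <- dat
n_r <- nrow(tab); n_c <- ncol(tab)
cells <- data.frame(
  row = rep(seq_len(n_r), n_c),
  col = rep(seq_len(n_c), each = n_r),
  text = unlist(lapply(tab, function(x) {
    if (is.numeric(x)) format(signif(x, 3)) else as.character(x)
  }), use.names = FALSE),
  bold = FALSE
)
cells <- rbind(data.frame(row = 0, col = seq_len(n_c), text = names(tab),
                          bold = TRUE), cells)
p <- ggplot(cells, aes(col, -row, label = text, fontface = ifelse(bold, 2, 1))) +
  geom_text(size = font.size / 3, hjust = 0, family = font.family) +
  annotate("segment", x = 0.9, xend = n_c + 0.9, y = -0.5, yend = -0.5,
           colour = line.colour) +
  scale_x_continuous(limits = c(0.9, n_c + 1)) +
  labs(title = "{{title}}") +
  theme_void(base_size = font.size) +
  theme(plot.title = element_text(face = "bold"))
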