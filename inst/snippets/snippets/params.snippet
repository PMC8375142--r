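
# --- shared visual parameters (edit here to restyle every plot) ---
font.size      <- 9
font.family    <- "sans"
line.colour    <- "grey30"
point.size     <- 1.2
jitter.width   <- 0.15
mean.colour    <- "red"
sig.colour     <- "red"
ns.colour      <- "black"
heat.low       <- "#08306B"   # darkest blue = lowest
heat.mid       <- "white"
heat.high      <- "#67000D"   # darkest red = highest
plot.dpi       <- {{dpi}}
image.formats  <- {{formats}}
plot.seed      <- 1           # fixes jitter so re-runs are identical

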