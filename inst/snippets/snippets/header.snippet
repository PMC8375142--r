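# {{title}}
# Auto-generated plot script: standalone and re-runnable. It reads the saved
# plot data file and regenerates the image without recomputing any analysis.
# Run from the scripts/ directory:  Rscript {{script_name}}

library(ggplot2)
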