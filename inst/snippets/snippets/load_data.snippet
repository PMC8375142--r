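
# --- plot data: exactly the values drawn ---
set.seed(plot.seed)
data.file <- "{{data_file}}"
dat <- read.delim(data.file, sep = "\t", header = TRUE, check.names = FALSE,
                  stringsAsFactors = FALSE)
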