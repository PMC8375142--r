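header
params
theme
save_function
load_data
plot_table
save_call
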