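
save_plot(p, "{{image_base}}", width = {{width}}, height = {{height}})
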