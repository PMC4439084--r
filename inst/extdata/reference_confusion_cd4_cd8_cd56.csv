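,CD4,CD8,CD56
CD4,135,84,12
CD8,81,149,1
CD56,24,4,148
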