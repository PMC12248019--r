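group target
338 R1242
033 R1254
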