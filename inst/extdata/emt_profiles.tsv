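CDH1	1	0
SNAI1	0	1
ZEB1	0	1
ZEB2	0	1
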