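# EMT core regulatory network (reconstructed from published interaction
# tables: SNAI1/ZEB transcription-factor core plus the miR-200/miR-203/
# miR-34 double-negative feedbacks).  SIF-signed dialect.
MIR200	-|	ZEB1
MIR200	-|	ZEB2
MIR203	-|	SNAI1
MIR203	-|	ZEB2
MIR34	-|	SNAI1
SNAI1	-|	MIR200
SNAI1	-|	MIR203
SNAI1	-|	MIR34
ZEB1	-|	MIR200
ZEB1	-|	MIR203
ZEB2	-|	MIR200
ZEB2	-|	MIR203
SNAI1	->	ZEB1
SNAI1	->	ZEB2
SNAI1	-|	CDH1
ZEB1	-|	CDH1
ZEB2	-|	CDH1
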