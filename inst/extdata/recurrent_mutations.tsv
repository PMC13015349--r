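condition	label	n_clones	denominator
GE_6day	chr11dup	84	179
GE_6day	SMF2	69	179
GE_6day	chr11dup+SMF2	1	179
gluc_5day	SSK1	7	71
gluc_5day	FPK1	10	71
gluc_5day	SXM1	10	71
GE_8day	FZF1	7	49
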