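gene	pathway
IRA1	Ras/PKA
IRA2	Ras/PKA
PDE2	Ras/PKA
GPB2	Ras/PKA
YAK1	Ras/PKA
SSK1	HOG
SSK2	HOG
FPK1	Ser/Thr kinase
SXM1	Nuclear transport
SMF2	Metal ion transport
SMF1	Metal ion transport
CCH1	Metal ion transport
FZF1	Sulfite metabolism TF
ACE2	Cytokinesis TF
RAV1	RAVE complex
IMH1	Vesicular transport
MPF1	Mitochondrial
RPA190	RNA Pol I
HSL7	Arginine methyltransferase
chr11dup	Chr11 duplication
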