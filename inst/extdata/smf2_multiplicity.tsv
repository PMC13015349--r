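mutations_per_clone	n_clones
1	71
2	5
5	1
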