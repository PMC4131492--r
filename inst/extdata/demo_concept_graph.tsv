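cui_a	relation	cui_b
C0000737	child_of	C0030193
C0553641	synonym	C0032961
C0549206	child_of	C0032961
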