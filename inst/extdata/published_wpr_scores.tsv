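pathway	sex	wpr
ALL	male	3.966
ALL	female	1.256
GABA	male	11.150
GABA	female	1.529
NEUROTRANSMISSION	male	6.090
NEUROTRANSMISSION	female	1.380
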