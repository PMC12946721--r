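trait	or	or_low	or_high	pval	or_digits
Acetobacterales	1.039	1.008	1.071	0.014	3
CD8 on naive CD8+ T cell	1.105	1.002	1.219	0.0458	3
PDGF_BB	0.864	0.751	0.994	0.0414	3
monocyte percentage of white cells	1.12	1.006	1.246	0.0376	2
N-acetylserine levels	1.534	1.007	2.336	0.0463	3
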