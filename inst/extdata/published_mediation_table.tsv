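exposure	mediator	outcome	total	direct	indirect	ci_low	ci_high	pval	proportion_pct
CAG-83 sp000435555	CD8 on naive CD8+ T cell	Schizophrenia	-0.060	-0.054	-0.006	-0.013	0.000	0.067	10.41
CAG-83 sp000435555	Caffeine to paraxanthine ratio	Schizophrenia	-0.060	-0.068	0.008	-0.020	0.035	0.584	12.54
Clostridium E sporosphaeroides	CD19 on IgD+ CD38+ B cell	Schizophrenia	0.269	0.254	0.016	-0.027	0.059	0.479	5.78
Clostridium E sporosphaeroides	Erythritol levels	Schizophrenia	0.269	0.231	0.039	-0.014	0.091	0.146	14.36
Clostridium E sporosphaeroides	X-17690 levels	Schizophrenia	0.269	0.226	0.044	-0.008	0.095	0.096	16.16
Faecalibacterium sp002160895	X-19438 levels	Schizophrenia	-0.258	-0.268	0.011	-0.011	0.033	0.341	4.18
Ruminococcus C sp000437255	Sphinganine-1-phosphate levels	Schizophrenia	0.086	0.090	-0.003	-0.008	0.001	0.112	3.87
Ruminococcus C sp000437255	Caffeine to paraxanthine ratio	Schizophrenia	0.086	0.076	0.010	-0.017	0.037	0.475	11.49
UBA1407	X-18921 levels	Schizophrenia	-0.382	-0.351	-0.031	-0.076	0.023	0.185	8.08
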