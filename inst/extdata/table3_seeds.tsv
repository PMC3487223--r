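group	seed	n_entities	reported_p
expression_target	INS	16	1.37e-06
expression_target	STAT3	8	6.46e-04
expression_target	PGR	5	1.02e-03
expression_target	SP1	15	1.21e-03
expression_target	NR3C1	7	1.43e-03
expression_target	JUN	8	1.48e-03
expression_target	AKT1	8	2.10e-03
expression_target	CEBPA	8	3.63e-03
expression_target	SMAD	5	3.92e-03
expression_target	IGF1	8	4.86e-03
expression_target	SMAD3	5	5.56e-03
expression_target	HGF	6	5.59e-03
expression_target	SRC	5	6.62e-03
expression_target	Cytokine	13	6.86e-03
expression_target	HIF1A	6	7.38e-03
expression_target	PI3K	8	8.94e-03
expression_target	NF-kB	11	8.97e-03
expression_target	TP53	9	9.81e-03
expression_target	Jun/Fos	9	1.12e-02
expression_target	STAT	5	1.55e-02
expression_target	CTNNB1	5	1.67e-02
expression_target	PKC	8	1.69e-02
expression_target	IL-6	8	1.71e-02
expression_target	Endotoxin	5	2.32e-02
expression_target	IL-1beta	8	2.35e-02
expression_target	IFNG	10	2.96e-02
expression_target	TNF	11	3.75e-02
expression_target	EP300	5	4.67e-02
expression_target	TGFB1	10	4.86e-02
expression_target	LEP	5	4.91e-02
binding_partner	Vitamin D	4	2.81e-05
binding_partner	GAPDH	4	7.44e-04
binding_partner	HDL	4	1.36e-03
binding_partner	APP	4	1.92e-03
binding_partner	Myosin	4	3.63e-03
binding_partner	Tubulin	6	5.21e-03
binding_partner	ATP	4	4.82e-02
protein_modification_target	Trypsin	6	4.39e-03
protein_modification_target	GST	4	8.28e-03
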