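# scheme: KIR2DL1_245
# gene: 2DL1
# position: 245
# version: 2026.1
# Transmembrane residue 245 dimorphism: R245 alleles (*002/001g, *003,
# etc.) signal more strongly than C245 alleles (*004, *007). The "001g"
# group is expanded here as the *001 allele group.
gene	allele_field	group	residue	position
2DL1	001	R245	R	245
2DL1	002	R245	R	245
2DL1	003	R245	R	245
2DL1	004	C245	C	245
2DL1	007	C245	C	245
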