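# scheme: KIR3DL1_expr
# gene: 3DL1
# version: 2026.1
# KIR3DL1 surface-expression classes: high (e.g. *001, *002, *008, *015,
# *020), low (e.g. *005, *007), and the non-expressed null allele *004.
gene	allele_field	group	residue	position
3DL1	001	high	NA	NA
3DL1	002	high	NA	NA
3DL1	008	high	NA	NA
3DL1	015	high	NA	NA
3DL1	020	high	NA	NA
3DL1	005	low	NA	NA
3DL1	007	low	NA	NA
3DL1	004	null	NA	NA
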