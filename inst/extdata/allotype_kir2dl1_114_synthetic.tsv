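# scheme: KIR2DL1_114
# gene: 2DL1
# position: 114
# version: 2026.1-synthetic
# SYNTHETIC PLACEHOLDER: a curated residue-114 (P114/L114) assignment
# could not be compiled from primary alignment data; this grouping exists
# so the scheme machinery can be exercised and must be replaced with a
# table derived from IPD-KIR protein alignments before scientific use.
gene	allele_field	group	residue	position
2DL1	001	P114	P	114
2DL1	002	P114	P	114
2DL1	003	P114	P	114
2DL1	004	L114	L	114
2DL1	007	L114	L	114
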