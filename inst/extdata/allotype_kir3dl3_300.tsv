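# scheme: KIR3DL3_300
# gene: 3DL3
# position: 300
# version: 2026.1
# Grouping of KIR3DL3 allele groups by the residue at mature-protein
# position 300 (transmembrane domain). N300/H300 differ by the missense
# change Asn>His; Y300 alleles are absent in Chinese Han populations.
gene	allele_field	group	residue	position
3DL3	001	N300	N	300
3DL3	006	N300	N	300
3DL3	002	H300	H	300
3DL3	008	H300	H	300
3DL3	009	H300	H	300
3DL3	003	Y300	Y	300
3DL3	004	Y300	Y	300
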