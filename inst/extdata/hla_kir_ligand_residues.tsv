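# table: hla_kir_ligand_residues
# version: 2026.1
# KIR-ligand epitope assignment for common class I alleles of the Chinese
# Han population. HLA-C alleles split into C1 (Ser77/Asn80, ligand of
# KIR2DL2/3) and C2 (Asn77/Lys80, ligand of KIR2DL1); HLA-B alleles carry
# the Bw4 motif (ligand of KIR3DL1, subtyped by residue 80: Ile80 binds
# more strongly than Thr80) or the non-ligand Bw6 motif (Ser77/Asn80).
# B*46:01 and B*73:01 additionally carry the C1 epitope; they are listed
# as Bw6 here and handled by the c1_bearing_b option of
# build_ligand_profile().
locus	allele	res77	res80	epitope
C	C*01:02	S	N	C1
C	C*03:02	S	N	C1
C	C*03:03	S	N	C1
C	C*03:04	S	N	C1
C	C*07:01	S	N	C1
C	C*07:02	S	N	C1
C	C*07:04	S	N	C1
C	C*08:01	S	N	C1
C	C*08:02	S	N	C1
C	C*12:02	S	N	C1
C	C*12:03	S	N	C1
C	C*14:02	S	N	C1
C	C*14:03	S	N	C1
C	C*16:01	S	N	C1
C	C*02:02	N	K	C2
C	C*04:01	N	K	C2
C	C*04:03	N	K	C2
C	C*05:01	N	K	C2
C	C*06:02	N	K	C2
C	C*15:02	N	K	C2
C	C*15:05	N	K	C2
C	C*16:02	N	K	C2
C	C*17:01	N	K	C2
B	B*07:02	S	N	Bw6
B	B*07:05	S	N	Bw6
B	B*08:01	S	N	Bw6
B	B*15:01	S	N	Bw6
B	B*15:02	S	N	Bw6
B	B*15:11	S	N	Bw6
B	B*35:01	S	N	Bw6
B	B*39:01	S	N	Bw6
B	B*40:01	S	N	Bw6
B	B*40:02	S	N	Bw6
B	B*46:01	S	N	Bw6
B	B*48:01	S	N	Bw6
B	B*54:01	S	N	Bw6
B	B*55:02	S	N	Bw6
B	B*56:01	S	N	Bw6
B	B*67:01	S	N	Bw6
B	B*13:01	N	I	Bw4-80I
B	B*13:02	N	I	Bw4-80I
B	B*38:02	N	I	Bw4-80I
B	B*51:01	N	I	Bw4-80I
B	B*51:02	N	I	Bw4-80I
B	B*52:01	N	I	Bw4-80I
B	B*53:01	N	I	Bw4-80I
B	B*57:01	N	I	Bw4-80I
B	B*58:01	N	I	Bw4-80I
B	B*59:01	N	I	Bw4-80I
B	B*27:05	D	T	Bw4-80T
B	B*37:01	D	T	Bw4-80T
B	B*44:02	D	T	Bw4-80T
B	B*44:03	D	T	Bw4-80T
B	B*47:01	D	T	Bw4-80T
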