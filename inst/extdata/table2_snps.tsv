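pos	ref	alt	gene	codon_a	codon_b	aa_a	aa_b	annotation
11124523	A	T	Csa4M286960.1	TTT	TAT	F	Y	Lipoxygenase
11126210	T	G	Csa4M286960.1	CCT	CCG	P	P	Lipoxygenase
11126739	A	G	Csa4M286960.1	TTA	TTG	L	L	Lipoxygenase
11135803	T	C	Csa4M286980.1	GAC	GAT	D	D	Lipoxygenase
11135804	A	G	Csa4M286980.1	GAT	AAT	D	N	Lipoxygenase
11135807	T	G	Csa4M286980.1	TGA	GGA	*	G	Lipoxygenase
11141217	A	G	Csa4M286990.1	ACG	ACA	T	T	Lipoxygenase
11144638	C	G	Csa4M287010.1	GCG	GGG	A	G	Lipoxygenase
11166969	T	G	Csa4M287550.1	TGG	TTG	W	L	Lipoxygenase
11167955	A	C	Csa4M287550.1	GCT	GAT	A	D	Lipoxygenase
11168050	C	G	Csa4M287550.1	GTT	CTT	V	L	Lipoxygenase
11168212	T	C	Csa4M287550.1	TAT	TAC	Y	Y	Lipoxygenase
11168253	T	C	Csa4M287550.1	GTT	GCT	V	A	Lipoxygenase
11173198	A	G	Csa4M287570.1	ACA	ATA	T	I	Unknown protein
11178904	A	G	Csa4M288070.1	TGG	TAG	W	*	Lipoxygenase
11179163	T	G	Csa4M288070.1	TTG	TTT	L	F	Lipoxygenase
11181197	T	C	Csa4M288070.1	TCG	TTG	S	L	Lipoxygenase
11181330	A	G	Csa4M288070.1	CAA	CAG	Q	Q	Lipoxygenase
11181348	A	G	Csa4M288070.1	CAG	CAA	Q	Q	Lipoxygenase
11181801	T	G	Csa4M288070.1	TCG	TCT	S	S	Lipoxygenase
11181936	T	C	Csa4M288070.1	GAT	GAC	D	D	Lipoxygenase
11181988	A	G	Csa4M288070.1	GAT	AAT	D	N	Lipoxygenase
11182010	T	C	Csa4M288070.1	CCT	CTT	P	L	Lipoxygenase
11182070	A	G	Csa4M288070.1	GAA	GGA	E	G	Lipoxygenase
11182092	A	G	Csa4M288070.1	CAG	CAA	Q	Q	Lipoxygenase
11182243	T	C	Csa4M288070.1	TTT	TTC	F	F	Lipoxygenase
11190230	T	C	Csa4M288080.1	ATC	ACC	I	T	Lipoxygenase
11192106	T	C	Csa4M288080.1	ACT	ATT	T	I	Lipoxygenase
11192300	A	G	Csa4M288080.1	GTA	GTG	V	V	Lipoxygenase
11192333	A	G	Csa4M288080.1	CAA	CAG	Q	Q	Lipoxygenase
11192417	T	C	Csa4M288080.1	CTC	CTT	L	L	Lipoxygenase
11193182	T	C	Csa4M288080.1	CCT	TCT	P	S	Lipoxygenase
11203061	A	G	Csa4M288110.1	GCG	GCA	A	A	Lipoxygenase
11203109	T	C	Csa4M288110.1	TCC	TCT	S	S	Lipoxygenase
11203161	A	T	Csa4M288110.1	TAT	AAT	Y	N	Lipoxygenase
11216771	A	G	Csa4M288610.1	ACG	ACA	T	T	Lipoxygenase
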