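table_id	name	codon	aa
1	Standard	TTT	F
1	Standard	TTC	F
1	Standard	TTA	L
1	Standard	TTG	L
1	Standard	TCT	S
1	Standard	TCC	S
1	Standard	TCA	S
1	Standard	TCG	S
1	Standard	TAT	Y
1	Standard	TAC	Y
1	Standard	TAA	*
1	Standard	TAG	*
1	Standard	TGT	C
1	Standard	TGC	C
1	Standard	TGA	*
1	Standard	TGG	W
1	Standard	CTT	L
1	Standard	CTC	L
1	Standard	CTA	L
1	Standard	CTG	L
1	Standard	CCT	P
1	Standard	CCC	P
1	Standard	CCA	P
1	Standard	CCG	P
1	Standard	CAT	H
1	Standard	CAC	H
1	Standard	CAA	Q
1	Standard	CAG	Q
1	Standard	CGT	R
1	Standard	CGC	R
1	Standard	CGA	R
1	Standard	CGG	R
1	Standard	ATT	I
1	Standard	ATC	I
1	Standard	ATA	I
1	Standard	ATG	M
1	Standard	ACT	T
1	Standard	ACC	T
1	Standard	ACA	T
1	Standard	ACG	T
1	Standard	AAT	N
1	Standard	AAC	N
1	Standard	AAA	K
1	Standard	AAG	K
1	Standard	AGT	S
1	Standard	AGC	S
1	Standard	AGA	R
1	Standard	AGG	R
1	Standard	GTT	V
1	Standard	GTC	V
1	Standard	GTA	V
1	Standard	GTG	V
1	Standard	GCT	A
1	Standard	GCC	A
1	Standard	GCA	A
1	Standard	GCG	A
1	Standard	GAT	D
1	Standard	GAC	D
1	Standard	GAA	E
1	Standard	GAG	E
1	Standard	GGT	G
1	Standard	GGC	G
1	Standard	GGA	G
1	Standard	GGG	G
6	Ciliate Nuclear	TTT	F
6	Ciliate Nuclear	TTC	F
6	Ciliate Nuclear	TTA	L
6	Ciliate Nuclear	TTG	L
6	Ciliate Nuclear	TCT	S
6	Ciliate Nuclear	TCC	S
6	Ciliate Nuclear	TCA	S
6	Ciliate Nuclear	TCG	S
6	Ciliate Nuclear	TAT	Y
6	Ciliate Nuclear	TAC	Y
6	Ciliate Nuclear	TAA	Q
6	Ciliate Nuclear	TAG	Q
6	Ciliate Nuclear	TGT	C
6	Ciliate Nuclear	TGC	C
6	Ciliate Nuclear	TGA	*
6	Ciliate Nuclear	TGG	W
6	Ciliate Nuclear	CTT	L
6	Ciliate Nuclear	CTC	L
6	Ciliate Nuclear	CTA	L
6	Ciliate Nuclear	CTG	L
6	Ciliate Nuclear	CCT	P
6	Ciliate Nuclear	CCC	P
6	Ciliate Nuclear	CCA	P
6	Ciliate Nuclear	CCG	P
6	Ciliate Nuclear	CAT	H
6	Ciliate Nuclear	CAC	H
6	Ciliate Nuclear	CAA	Q
6	Ciliate Nuclear	CAG	Q
6	Ciliate Nuclear	CGT	R
6	Ciliate Nuclear	CGC	R
6	Ciliate Nuclear	CGA	R
6	Ciliate Nuclear	CGG	R
6	Ciliate Nuclear	ATT	I
6	Ciliate Nuclear	ATC	I
6	Ciliate Nuclear	ATA	I
6	Ciliate Nuclear	ATG	M
6	Ciliate Nuclear	ACT	T
6	Ciliate Nuclear	ACC	T
6	Ciliate Nuclear	ACA	T
6	Ciliate Nuclear	ACG	T
6	Ciliate Nuclear	AAT	N
6	Ciliate Nuclear	AAC	N
6	Ciliate Nuclear	AAA	K
6	Ciliate Nuclear	AAG	K
6	Ciliate Nuclear	AGT	S
6	Ciliate Nuclear	AGC	S
6	Ciliate Nuclear	AGA	R
6	Ciliate Nuclear	AGG	R
6	Ciliate Nuclear	GTT	V
6	Ciliate Nuclear	GTC	V
6	Ciliate Nuclear	GTA	V
6	Ciliate Nuclear	GTG	V
6	Ciliate Nuclear	GCT	A
6	Ciliate Nuclear	GCC	A
6	Ciliate Nuclear	GCA	A
6	Ciliate Nuclear	GCG	A
6	Ciliate Nuclear	GAT	D
6	Ciliate Nuclear	GAC	D
6	Ciliate Nuclear	GAA	E
6	Ciliate Nuclear	GAG	E
6	Ciliate Nuclear	GGT	G
6	Ciliate Nuclear	GGC	G
6	Ciliate Nuclear	GGA	G
6	Ciliate Nuclear	GGG	G
15	Blepharisma Nuclear	TTT	F
15	Blepharisma Nuclear	TTC	F
15	Blepharisma Nuclear	TTA	L
15	Blepharisma Nuclear	TTG	L
15	Blepharisma Nuclear	TCT	S
15	Blepharisma Nuclear	TCC	S
15	Blepharisma Nuclear	TCA	S
15	Blepharisma Nuclear	TCG	S
15	Blepharisma Nuclear	TAT	Y
15	Blepharisma Nuclear	TAC	Y
15	Blepharisma Nuclear	TAA	*
15	Blepharisma Nuclear	TAG	Q
15	Blepharisma Nuclear	TGT	C
15	Blepharisma Nuclear	TGC	C
15	Blepharisma Nuclear	TGA	*
15	Blepharisma Nuclear	TGG	W
15	Blepharisma Nuclear	CTT	L
15	Blepharisma Nuclear	CTC	L
15	Blepharisma Nuclear	CTA	L
15	Blepharisma Nuclear	CTG	L
15	Blepharisma Nuclear	CCT	P
15	Blepharisma Nuclear	CCC	P
15	Blepharisma Nuclear	CCA	P
15	Blepharisma Nuclear	CCG	P
15	Blepharisma Nuclear	CAT	H
15	Blepharisma Nuclear	CAC	H
15	Blepharisma Nuclear	CAA	Q
15	Blepharisma Nuclear	CAG	Q
15	Blepharisma Nuclear	CGT	R
15	Blepharisma Nuclear	CGC	R
15	Blepharisma Nuclear	CGA	R
15	Blepharisma Nuclear	CGG	R
15	Blepharisma Nuclear	ATT	I
15	Blepharisma Nuclear	ATC	I
15	Blepharisma Nuclear	ATA	I
15	Blepharisma Nuclear	ATG	M
15	Blepharisma Nuclear	ACT	T
15	Blepharisma Nuclear	ACC	T
15	Blepharisma Nuclear	ACA	T
15	Blepharisma Nuclear	ACG	T
15	Blepharisma Nuclear	AAT	N
15	Blepharisma Nuclear	AAC	N
15	Blepharisma Nuclear	AAA	K
15	Blepharisma Nuclear	AAG	K
15	Blepharisma Nuclear	AGT	S
15	Blepharisma Nuclear	AGC	S
15	Blepharisma Nuclear	AGA	R
15	Blepharisma Nuclear	AGG	R
15	Blepharisma Nuclear	GTT	V
15	Blepharisma Nuclear	GTC	V
15	Blepharisma Nuclear	GTA	V
15	Blepharisma Nuclear	GTG	V
15	Blepharisma Nuclear	GCT	A
15	Blepharisma Nuclear	GCC	A
15	Blepharisma Nuclear	GCA	A
15	Blepharisma Nuclear	GCG	A
15	Blepharisma Nuclear	GAT	D
15	Blepharisma Nuclear	GAC	D
15	Blepharisma Nuclear	GAA	E
15	Blepharisma Nuclear	GAG	E
15	Blepharisma Nuclear	GGT	G
15	Blepharisma Nuclear	GGC	G
15	Blepharisma Nuclear	GGA	G
15	Blepharisma Nuclear	GGG	G
16	Chlorophycean Mitochondrial	TTT	F
16	Chlorophycean Mitochondrial	TTC	F
16	Chlorophycean Mitochondrial	TTA	L
16	Chlorophycean Mitochondrial	TTG	L
16	Chlorophycean Mitochondrial	TCT	S
16	Chlorophycean Mitochondrial	TCC	S
16	Chlorophycean Mitochondrial	TCA	S
16	Chlorophycean Mitochondrial	TCG	S
16	Chlorophycean Mitochondrial	TAT	Y
16	Chlorophycean Mitochondrial	TAC	Y
16	Chlorophycean Mitochondrial	TAA	*
16	Chlorophycean Mitochondrial	TAG	L
16	Chlorophycean Mitochondrial	TGT	C
16	Chlorophycean Mitochondrial	TGC	C
16	Chlorophycean Mitochondrial	TGA	*
16	Chlorophycean Mitochondrial	TGG	W
16	Chlorophycean Mitochondrial	CTT	L
16	Chlorophycean Mitochondrial	CTC	L
16	Chlorophycean Mitochondrial	CTA	L
16	Chlorophycean Mitochondrial	CTG	L
16	Chlorophycean Mitochondrial	CCT	P
16	Chlorophycean Mitochondrial	CCC	P
16	Chlorophycean Mitochondrial	CCA	P
16	Chlorophycean Mitochondrial	CCG	P
16	Chlorophycean Mitochondrial	CAT	H
16	Chlorophycean Mitochondrial	CAC	H
16	Chlorophycean Mitochondrial	CAA	Q
16	Chlorophycean Mitochondrial	CAG	Q
16	Chlorophycean Mitochondrial	CGT	R
16	Chlorophycean Mitochondrial	CGC	R
16	Chlorophycean Mitochondrial	CGA	R
16	Chlorophycean Mitochondrial	CGG	R
16	Chlorophycean Mitochondrial	ATT	I
16	Chlorophycean Mitochondrial	ATC	I
16	Chlorophycean Mitochondrial	ATA	I
16	Chlorophycean Mitochondrial	ATG	M
16	Chlorophycean Mitochondrial	ACT	T
16	Chlorophycean Mitochondrial	ACC	T
16	Chlorophycean Mitochondrial	ACA	T
16	Chlorophycean Mitochondrial	ACG	T
16	Chlorophycean Mitochondrial	AAT	N
16	Chlorophycean Mitochondrial	AAC	N
16	Chlorophycean Mitochondrial	AAA	K
16	Chlorophycean Mitochondrial	AAG	K
16	Chlorophycean Mitochondrial	AGT	S
16	Chlorophycean Mitochondrial	AGC	S
16	Chlorophycean Mitochondrial	AGA	R
16	Chlorophycean Mitochondrial	AGG	R
16	Chlorophycean Mitochondrial	GTT	V
16	Chlorophycean Mitochondrial	GTC	V
16	Chlorophycean Mitochondrial	GTA	V
16	Chlorophycean Mitochondrial	GTG	V
16	Chlorophycean Mitochondrial	GCT	A
16	Chlorophycean Mitochondrial	GCC	A
16	Chlorophycean Mitochondrial	GCA	A
16	Chlorophycean Mitochondrial	GCG	A
16	Chlorophycean Mitochondrial	GAT	D
16	Chlorophycean Mitochondrial	GAC	D
16	Chlorophycean Mitochondrial	GAA	E
16	Chlorophycean Mitochondrial	GAG	E
16	Chlorophycean Mitochondrial	GGT	G
16	Chlorophycean Mitochondrial	GGC	G
16	Chlorophycean Mitochondrial	GGA	G
16	Chlorophycean Mitochondrial	GGG	G
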