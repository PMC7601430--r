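# Per-trait miRNA -> suppressed-gene attributions from the reconstructed
# trait networks. Genes in the global suppressed list that were never
# attributed to a named miRNA appear with trait ALL and an empty mirna field
# (they count as suppressed targets but contribute no edge).
# note: not_in_table2 marks a suppressed gene absent from every trait window.
trait	mirna	gene	note
BT	bta-miR-124a	EXO1
BT	bta-miR-124a	CLASP1
BT	bta-miR-124a	NIFK
BT	bta-miR-2379	EXO1
BT	bta-miR-2379	NIPA1
BT	bta-miR-2379	PRELID1
BT	bta-miR-2379	RALGAPA2
BT	bta-miR-2379	SLC31A1
CW	bta-miR-124a	C14H8orf46
CW	bta-miR-124a	PPP1R42
CW	bta-miR-124a	STK32A
CW	bta-miR-124a	ZHX1
CW	bta-miR-2379	ATP6V1H
CW	bta-miR-2379	DERL1
CW	bta-miR-2379	FAM91A1
CW	bta-miR-2379	NSMCE2
CW	bta-miR-2379	PRELID2
CW	bta-miR-2379	SGK3
CW	bta-miR-2379	TMEM68
CW	bta-miR-3064	CGA
EMA	bta-miR-2379	ATP6V1H
EMA	bta-miR-2379	SMURF2
EMA	bta-miR-2379	TMEM68
MS	bta-miR-124a	ABT1
MS	bta-miR-2379	ATP6V1H
MS	bta-miR-2379	FAM91A1
MS	bta-miR-2379	NSMCE2
MS	bta-miR-2379	SGK3
MS	bta-miR-2379	TMEM68
MS	bta-miR-3064	RNF111
MS	bta-miR-3064	SLTM
YW	bta-miR-124a	C14H8orf46
YW	bta-miR-124a	PPARGC1A
YW	bta-miR-124a	PPP1R42
YW	bta-miR-2379	ATP6V1H
YW	bta-miR-2379	FAM91A1
YW	bta-miR-2379	NSMCE2
YW	bta-miR-2379	SGK3
YW	bta-miR-2379	TMEM68
YW	bta-miR-3064	RNF111
YW	bta-miR-3064	SLTM
ALL		ATF7IP
ALL		B3GNT2
ALL		C19H17orf58
ALL		CCDC115
ALL		CDKN1B
ALL		FAM135B
ALL		FAM234B
ALL		FAM83A
ALL		GRK7
ALL		HEBP1
ALL		NKAIN3
ALL		PPM1L	not_in_table2
ALL		PXYLP1
ALL		RNF7
ALL		ST18
ALL		TFDP2
ALL		TRIM55
ALL		ZNF346
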