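hsa05014	Amyotrophic lateral sclerosis (ALS)	CASP3	NOS1	GRIA2	GRIN2A	TP53	NEFL	NEFM
hsa04062	Chemokine signaling pathway	MAPK1	IL8	GRB2	ARRB1	PTK2B	JAK2	ADRBK1	STAT1	VAV1	STAT3
hsa04722	Neurotrophin signaling pathway	MAPK1	PSEN1	CAMK4	GRB2	JUN	GAB1	TP53
hsa05010	Alzheimer's disease	MAPK1	APP	CDK5R1	CASP3	NOS1	PSEN1	BACE1	GRIN2A
hsa04650	Natural killer cell mediated cytotoxicity	MAPK1	CASP3	GRB2	PTK2B	ICAM2	LCK	VAV1
hsa04720	Long-term potentiation	MAPK1	EP300	CAMK4	GRIA2	GRIN2A
hsa04660	T cell receptor signaling pathway	MAPK1	GRB2	JUN	LCK	CD4	VAV1
hsa04662	B cell receptor signaling pathway	MAPK1	CR2	GRB2	JUN	VAV1
hsa04520	Adherens junction	MAPK1	EP300	SMAD3	CDH1	SRC
hsa04020	Calcium signaling pathway	NOS1	CAMK4	SPHK2	CHRM3	PTK2B	GRIN2A	NOS3
hsa04012	ErbB signaling pathway	MAPK1	GRB2	JUN	GAB1	SRC
hsa04350	TGF-beta signaling pathway	MAPK1	EP300	SP1	SMAD3	DCN
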