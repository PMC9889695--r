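# Example CRE catalog: widely used plant consensus sequences from the
# general literature. This is a convenience fixture for examples and
# simulations; it is not a transcription of any specific database release.
cre_id	display_name	variants	tfs	tags
W_BOX	W box	TTGACC,TTGACT	WRKY	stress,SA,JA,ABA
GATA_BOX	GATA box	WGATAR	GATA factors	light,growth,CK,GA,BR
E_BOX	E box	CANNTG	bHLH112	stress,ABA,JA,BR
I_BOX	I box	GATAAG	I-box binding factors	light
ARR1_BINDING	ARR1-binding site	NGATT	ARR1	growth,CK
DOF_BINDING	Dof-binding site	AAAG	Dof	light,SA,GA,BR
GT1_BINDING	GT-1 binding site	GRWAAW	GT-1	light,stress
MYB_BINDING	MYB-binding site	WAACCA,CNGTTR	MYB1,MYB2	stress,ABA,CK
MYC_RECOGNITION	MYC recognition site	CACATG	MYC2,ICE1	stress,ABA,JA
ACGT_BOX	ACGT box	ACGT	bZIP factors	stress,ABA,SA
RAV1_BINDING	RAV1-binding site	CAACA	RAV1	stress,CK,BR
SORLIP	SORLIP motif	GCCAC	SORLIP factors	light
CCAAT_BOX	CCAAT box	CCAAT	NF-Y	growth,stress
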