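# Published per-CRE percent columns for the over-represented tier listing:
# percent of up- / down-regulated isoprene-responsive genes whose 3-kb
# promoter carries the CRE. Blank = CRE absent from that set's listing.
cre_id	percent_up	percent_down
ARR1_binding_site	100	
Dof_binding_site	100	
DRE_like_motif	100	96
E_box	100	
GATA_box	100	94
GT1_binding_site	100	
MYB_binding_site	100	92
SEF_binding_motif	100	
W_box	100	75
ROOTMOTIFTAPOX1	98	
OSE1_2ROOTNODULE	97	
CACTFTPPCA1	95	
GTGA_motif	95	
I_box	95	75
POLLEN1_LELAT52	95	
RAV1_binding_site	95	90
BIHD1	84	
MYC_recognition_site	84	73
CCAAT_box_1	82	
EEC_consensus_motif	82	
SORLIP	79	84
ACGT_box	75	
LFY	70	75
T_box	69	75
ATB2_motif	67	75
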