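# Published per-CRE percent columns for the moderately-over-represented tier
# listing. Blank = CRE absent from that set's listing (the source prints
# tier cross-references, not percentages, in three up-set cells).
cre_id	percent_up	percent_down
ABRE_like_binding_site	74	
RE_alpha	72	
CuRE	70	
LFY_binding_site	70	
Pyrimidine_box	69	
GARE	67	
SURE	67	
PREAT	67	
CArG_motif	66	
MARTBOX	64	
ARF_element	64	69
minus10_PEHVPSBD	59	
AMYBOX1	57	
HD_ZIP_L1_box	57	65
LTRE_motif	57	
CPB_binding_motif	56	
BBF1_binding_motif	56	
TATCCAY_motif	52	
ASF1_binding_site	51	
MYC_recognition_site		73
Box_II		71
CCA1_binding_site		57
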