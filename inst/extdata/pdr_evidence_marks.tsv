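gene	smr_fdr_fin	heidi_fin	smr_fdr_blood	heidi_blood	smr_fdr_rep	heidi_rep	mr_p_fin	mr_p_8cohort	coloc_pp4
CTSH	1	1	1	1	1	1	1	1	1
CYP21A2	1	0	1	1	1	1	1	1	0
MICB	1	1	1	1	1	1	0	0	0
CCNE2	1	1	0	0	0	0	1	0	1
TP53INP1	1	0	1	1	0	0	0	0	1
PPIP5K2	1	1	0	0	0	0	0	0	1
XRCC1	1	1	0	0	0	0	0	0	1
C4B	1	0	1	0	0	0	1	0	0
C4A	1	0	1	0	0	0	1	0	0
HLA-C	1	0	1	0	0	0	1	0	0
ZBTB22	1	0	1	1	0	0	0	0	0
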