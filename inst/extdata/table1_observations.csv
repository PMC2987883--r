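node,sign
mRNA_RAS,+
mRNA_CCNE_,+
mRNA_NFKB_,+
mRNA_PIK3C_,+
mRNA_PIK3R_,-
mRNA_RAC_,+
mRNA_RHO_,+
mRNA_TGFB_,+
mRNA_TNF_,+
mRNA_AKT1,+
mRNA_CDKN1A,+
mRNA_CDKN1C,+
mRNA_CYCS,-
mRNA_E2F5,-
mRNA_ECM1,+
mRNA_ECM2,+
mRNA_FAS,-
mRNA_FASLG,+
mRNA_IER3,+
mRNA_IGF1,-
mRNA_IGFBP3,+
mRNA_JUN,+
mRNA_MAPK8,+
mRNA_MYC,-
mRNA_MYCBP,-
mRNA_PDGFRB,+
mRNA_PRKCB1,-
mRNA_RASA1,+
mRNA_RBL2,-
mRNA_SKP2,+
mRNA_SOS2,+
mRNA_TNFAIP3,+
mRNA_TNFRSF1A,+
EWS-FLI1,-
Cell_Cycle_Anaphase,-
Cell_Cycle_G2,-
Cell_Cycle_M,-
Cell_Cycle_S,-
Cell_Migration,-
Apoptosis,+
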