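node,sign
mRNA_AKT1,+
mRNA_IGF1,-
mRNA_IGFBP3,+
mRNA_PDGFRB,+
mRNA_PIK3R_,-
mRNA_RAC_,+
mRNA_RHO_,+
Cell_Migration,-
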