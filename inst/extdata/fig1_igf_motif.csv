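source,target,sign,level
(.RAS),(PIK3C.),+,post_translational
(.RAS),IGFBP3,-,post_translational
IGF1,(PIK3C.),+,post_translational
IGF1,mRNA_AKT1,+,transcriptional
IGFBP3,IGF1,-,post_translational
mRNA_IGF1,IGF1,+,
mRNA_IGFBP3,IGFBP3,+,
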