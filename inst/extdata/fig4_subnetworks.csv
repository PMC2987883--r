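part,source,target,sign,level
A,EWS-FLI1,mRNA_TGFBR2,-,transcriptional
A,mRNA_TGFBR2,TGFBR2,+,
A,mRNA_IGF1,IGF1,+,
A,IGFBP3,IGF1,-,post_translational
A,IGF1,mRNA_AKT1,+,transcriptional
A,mRNA_IGFBP3,IGFBP3,+,
A,(.RAS),IGFBP3,-,post_translational
A,IGFBP3,mRNA_BCL2,-,transcriptional
A,TP73,mRNA_PDGFRB,-,transcriptional
A,TP73,mRNA_CDKN1C,+,transcriptional
A,IGF2,mRNA_CDKN1C,-,transcriptional
A,IGFBP3,IGF2,-,post_translational
A,mRNA_IGF2,IGF2,+,
A,(.RAS),(PIK3C.),+,post_translational
A,IGF1,(PIK3C.),+,post_translational
B,mRNA_JUN,JUN,+,
B,JUN,mRNA_FASLG,+,transcriptional
B,JUN,mRNA_TP53,-,transcriptional
B,mRNA_FASLG,FASLG,+,
C,mRNA_RHO_,(RHO.),+,
C,(RAC.),(RHO.),+,post_translational
C,(RAC.),Cell_Migration,+,post_translational
C,(RHO.),Cell_Migration,+,post_translational
D,mRNA_PRKCB1,PRKCB1,+,
D,PRKCB1,RB1_p,+,post_translational
E,((CCNA.)_p:CDC2),CDC2,+,post_translational
E,(CCNB1_p:CDC2),CDC2,+,post_translational
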