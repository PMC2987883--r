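node,sign,deduction,group,functional_type
(PIK3C.),+,FORWARD,family,III
(.RAS),+,BACKWARD,family,III
(RAC.),-,BACKWARD,family,I
(TGFB.),+,FORWARD,family,III
(TNF.),+,FORWARD,family,III
RB1_p,-,FORWARD,phospho,II
CDC2,-,FORWARD,protein,II
ECM1,+,FORWARD,protein,III
ECM2,+,FORWARD,protein,III
FASLG,+,FORWARD,protein,III
IER3,+,FORWARD,protein,III
IGF1,+,BACKWARD,protein,I
IGF2,-,BACKWARD,protein,II
IGFBP3,-,BACKWARD,protein,I
JUN,+,BACKWARD,protein,III
MYCBP,-,FORWARD,protein,III
PRKCB1,-,FORWARD,protein,III
RASA1,+,FORWARD,protein,III
SKP2,+,FORWARD,protein,III
TGFBR2,+,FORWARD,protein,II
TNFAIP3,+,FORWARD,protein,III
TP73,-,BACKWARD,protein,II
mRNA_BCL2,+,FORWARD,mRNA,
mRNA_IGF2,-,BACKWARD,mRNA,
mRNA_TGFBR2,+,FORWARD,mRNA,
mRNA_TP53,-,FORWARD,mRNA,
((CCNA.):CDK2),-,BACKWARD,complex,
((CCNA.)_p:CDC2),-,FORWARD,complex,
((CCNA.)_p:CDK2),-,FORWARD,complex,
(CCNB1:CDC2),-,BACKWARD,complex,
(CCNB1_p:CDC2),-,FORWARD,complex,
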