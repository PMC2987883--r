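source,target,sign,level
(.RAS),(PIK3C.),+,post_translational
(.RAS),IGFBP3,-,post_translational
(PIK3C.),AKT1,+,post_translational
(RAC.),(RHO.),+,post_translational
(RAC.),Cell_Migration,+,post_translational
(RHO.),Cell_Migration,+,post_translational
IGF1,(PIK3C.),+,post_translational
IGF1,AKT1,+,transcriptional
IGFBP3,IGF1,-,post_translational
PDGFRB,(PIK3R.),+,post_translational
SOS2,(RAC.),?,post_translational
mRNA_RHO_,(RHO.),+,
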