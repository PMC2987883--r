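source,target,sign,level
(RAC.),(RHO.),+,post_translational
(RAC.),Cell_Migration,+,post_translational
(RHO.),Cell_Migration,+,post_translational
PDGFRB,(PIK3R.),+,post_translational
mRNA_RHO_,(RHO.),+,
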