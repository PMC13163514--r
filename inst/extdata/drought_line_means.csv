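genotype,selection,gy_drought,gy_favorable,flowering_mean
ps_top,phenotypic,3.45,3.90,15.3
gs_top,genomic,3.75,4.25,16.5
gs_mid,genomic,3.19,4.96,19.9
gs_bottom,genomic,2.66,3.66,17.9
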