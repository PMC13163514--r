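water,soil,grain_yield,straw,harvest_index,flowering,maturity,height
drought,sandy_loam,3.67,4.33,0.456,15.7,76.8,102.5
drought,silty_clay,2.63,2.55,0.510,15.7,82.8,72.3
favorable,sandy_loam,4.31,5.19,0.449,16.1,81.3,108.7
favorable,silty_clay,3.49,4.44,0.446,16.3,90.3,92.1
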