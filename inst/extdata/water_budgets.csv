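activity,material,soil,sowing,bs,sa,ds,mf
training_bl,breeding_lines,sandy_loam,mid_february,30,120,50,240
training_lg,landraces,sandy_loam,mid_february,30,120,21,332
validation_sandy,breeding_lines_and_landraces,sandy_loam,mid_january,220,80,0,70
validation_silty,breeding_lines_and_landraces,silty_clay,mid_january,220,100,0,200
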