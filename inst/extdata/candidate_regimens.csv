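label,gfr,day1_dose,day1_int,day2_dose,day2_int,day3_dose,day3_int,maint_dose,maint_int
gfr120_load3_m15q24,120,15,12,15,24,15,24,15,24
gfr120_load5_m7.5q24,120,15,12,15,12,15,24,7.5,24
gfr120_load5_m15q24,120,15,12,15,12,15,24,15,24
gfr90_load3_m15q24,90,15,12,15,24,15,24,15,24
gfr90_load5_m7.5q24,90,15,12,15,12,15,24,7.5,24
gfr90_load5_m15q24,90,15,12,15,12,15,24,15,24
gfr60_load3_m7.5q24,60,15,12,15,24,15,24,7.5,24
gfr60_load3_m15q48,60,15,12,15,24,15,24,15,48
gfr30_load3_m7.5q24,30,15,12,15,24,15,24,7.5,24
gfr30_load3_m15q48,30,15,12,15,24,15,24,15,48
gfr15_load3_12_m12q72,15,12,12,12,24,12,24,12,72
gfr15_load3_m5q24,15,15,12,15,24,15,24,5,24
gfr15_load3_m15q72,15,15,12,15,24,15,24,15,72
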