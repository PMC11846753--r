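patient_id,age,sex,systolic_mmhg,diastolic_mmhg,vessel,label
P1,64,M,126,83,RCA,erosion
P2,58,M,117,73,LAD,erosion
P3,69,F,150,80,RCA,erosion
P4,64,M,105,72,LAD,erosion
P5,42,M,110,60,LAD,erosion
P6,41,M,97,56,LAD,erosion
P7,55,M,110,70,LAD,erosion
P8,46,M,136,88,LAD,erosion
P9,81,F,138,71,RCA,no_erosion
P10,72,M,143,80,LCX,no_erosion
P11,80,F,136,89,LCX,no_erosion
P12,80,F,136,89,RCA,no_erosion
P13,66,F,172,65,RCA,no_erosion
P14,73,M,150,55,LCX,no_erosion
P15,63,F,138,82,LAD,no_erosion
P16,61,M,128,78,LCX,no_erosion
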