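patient_id,label,mean_cap_thickness_um,min_cap_thickness_um,area_stenosis_pct,mean_plaque_burden_pct
P1,erosion,125,56,69.1,38.8
P2,erosion,397,150,79.8,56.5
P3,erosion,491,304,22.1,38.4
P4,erosion,149,63,72.7,58.7
P5,erosion,249,51,75.4,63.9
P6,erosion,326,130,77.2,42.5
P7,erosion,374,138,69.2,62.6
P8,erosion,360,145,58.1,62.5
P9,no_erosion,293,176,25.3,41.7
P10,no_erosion,350,234,53.9,48.9
P11,no_erosion,313,95,68.3,51.5
P12,no_erosion,255,91,35.6,46.6
P13,no_erosion,288,190,18.0,48.9
P14,no_erosion,517,287,50.2,46.7
P15,no_erosion,486,222,70.4,51.2
P16,no_erosion,652,324,74.0,57.6
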