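patient_id,label,max_pws_kpa,mean_pws_kpa,max_pwsn,mean_pwsn,max_fss_dyn_cm2,mean_fss_dyn_cm2,min_fss_dyn_cm2
P1,erosion,396.8,122.6,0.3724,0.1149,166.97,63.84,9.53
P2,erosion,144.8,63.9,0.1664,0.1048,121.29,47.00,4.95
P3,erosion,289.3,121.6,0.1726,0.1104,86.12,47.20,26.14
P4,erosion,191.1,67.1,0.1827,0.1032,119.73,50.57,8.94
P5,erosion,310.2,77.5,0.1689,0.0974,128.48,50.78,10.30
P6,erosion,182.2,83.3,0.1391,0.0932,96.21,22.29,4.38
P7,erosion,127.0,52.9,0.1542,0.0908,193.46,89.99,16.02
P8,erosion,302.7,76.7,0.2337,0.1147,111.41,22.20,5.65
P9,no_erosion,355.1,136.0,0.1943,0.1288,32.07,16.63,9.57
P10,no_erosion,238.8,104.1,0.1811,0.1130,96.06,48.59,19.06
P11,no_erosion,239.1,84.1,0.1786,0.0996,156.35,42.44,12.65
P12,no_erosion,184.3,96.2,0.1404,0.1129,73.04,36.10,18.60
P13,no_erosion,323.9,137.8,0.1781,0.1225,117.25,59.81,28.45
P14,no_erosion,244.1,125.2,0.1661,0.1174,21.16,10.66,3.83
P15,no_erosion,352.0,100.8,0.1828,0.1081,44.85,19.27,4.90
P16,no_erosion,171.7,78.5,0.2328,0.1056,40.71,10.84,2.65
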