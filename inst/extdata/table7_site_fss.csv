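patient_id,stat,with_erosion,without_erosion
P1,max,158.14,166.97
P2,max,53.22,121.29
P3,max,33.12,86.12
P4,max,119.73,119.54
P5,max,128.48,128.32
P6,max,96.21,93.27
P7,max,173.34,193.46
P8,max,100.08,111.41
P1,min,114.18,9.53
P2,min,51.58,4.95
P3,min,32.75,26.14
P4,min,41.97,8.94
P5,min,77.40,10.30
P6,min,7.34,4.38
P7,min,49.53,16.02
P8,min,6.41,5.65
P1,mean,130.65,62.82
P2,mean,52.63,46.99
P3,mean,32.94,47.22
P4,mean,80.93,48.60
P5,mean,105.19,48.13
P6,mean,54.56,18.90
P7,mean,94.18,89.82
P8,mean,21.06,22.43
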