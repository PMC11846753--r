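patient_id,quantity,with_erosion,without_erosion
P1,max_pws_kpa,286.9,396.8
P2,max_pws_kpa,80.1,144.8
P3,max_pws_kpa,168.2,289.3
P4,max_pws_kpa,93.1,191.1
P5,max_pws_kpa,165.1,310.2
P6,max_pws_kpa,76.9,182.2
P7,max_pws_kpa,70.2,127.0
P8,max_pws_kpa,113.0,302.7
P1,mean_pws_kpa,151.6,122.2
P2,mean_pws_kpa,79.0,63.9
P3,mean_pws_kpa,152.8,121.5
P4,mean_pws_kpa,56.8,67.7
P5,mean_pws_kpa,67.4,78.0
P6,mean_pws_kpa,40.2,87.8
P7,mean_pws_kpa,41.6,53.4
P8,mean_pws_kpa,62.1,79.6
P1,max_pwsn,0.1704,0.3724
P2,max_pwsn,0.1200,0.1664
P3,max_pwsn,0.1283,0.1726
P4,max_pwsn,0.1292,0.1827
P5,max_pwsn,0.1366,0.1689
P6,max_pwsn,0.0963,0.1391
P7,max_pwsn,0.1215,0.1542
P8,max_pwsn,0.1666,0.2337
P1,mean_pwsn,0.1290,0.1147
P2,mean_pwsn,0.1176,0.1048
P3,mean_pwsn,0.1220,0.1104
P4,mean_pwsn,0.0907,0.1040
P5,mean_pwsn,0.0941,0.0976
P6,mean_pwsn,0.0759,0.0950
P7,mean_pwsn,0.0844,0.0911
P8,mean_pwsn,0.1108,0.1155
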