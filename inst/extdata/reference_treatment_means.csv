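season,factor,level,ph_s,ec_e,wboc,kmno4_n,olsen_p,nh4oac_k
sorghum,tillage,CT,7.96,4.79,3.85,85.6,23.0,244.4
sorghum,tillage,RT,7.90,4.54,3.98,90.9,25.0,241.3
sorghum,tillage,ZT,7.93,4.28,3.99,86.3,22.6,250.2
sorghum,tillage,SE_m,0.06,0.25,0.19,2.12,0.82,4.25
sorghum,irrigation,CWR100,7.94,4.97,3.88,89.8,23.8,241.8
sorghum,irrigation,CWR80,7.95,4.40,3.96,87.2,24.0,240.7
sorghum,irrigation,CWR60,7.91,4.24,3.99,85.9,22.8,255.2
sorghum,irrigation,SE_m,0.04,0.18,0.15,1.62,0.65,5.39
sorghum,mulch,none,7.92,4.54,3.88,85.2,23.2,241.4
sorghum,mulch,mulch,7.94,4.53,4.01,90.0,23.9,249.3
sorghum,mulch,SE_m,0.03,0.15,0.12,1.32,0.53,4.40
wheat,tillage,CT,7.79,7.90,4.23,90.6,19.4,214.4
wheat,tillage,RT,7.76,7.83,4.20,91.9,23.3,226.2
wheat,tillage,ZT,7.76,7.18,4.44,91.8,21.0,230.1
wheat,tillage,SE_m,0.03,0.35,0.25,1.84,1.06,5.69
wheat,irrigation,CWR100,7.77,8.23,4.30,94.4,20.7,222.2
wheat,irrigation,CWR80,7.78,7.65,4.20,89.9,20.0,220.5
wheat,irrigation,CWR60,7.77,7.04,4.37,90.0,23.1,227.7
wheat,irrigation,SE_m,0.04,0.23,0.16,1.66,1.02,5.01
wheat,mulch,none,7.77,7.92,4.17,88.1,20.6,218.2
wheat,mulch,mulch,7.77,7.35,4.41,94.8,21.9,229.3
wheat,mulch,SE_m,0.03,0.19,0.13,1.36,0.83,4.09
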