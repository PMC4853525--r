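label,age_low,age_high,gender,role,population_millions,prop_viewed,prop_lo,prop_hi,gross_alcohol,gross_alcohol_lo,gross_alcohol_hi,gross_tobacco,gross_tobacco_lo,gross_tobacco_hi,pc_alcohol,pc_alcohol_lo,pc_alcohol_hi,pc_tobacco,pc_tobacco_lo,pc_tobacco_hi
Adolescents,11,19,all,summary,5.91,0.22,0.19,0.26,308.19,256.44,359.93,62.17,51.73,72.60,52.11,43.36,60.86,10.51,8.75,12.28
Adolescents female,11,19,female,summary,2.88,0.28,0.23,0.33,186.35,152.98,219.71,37.59,30.86,44.32,64.66,53.09,76.24,13.04,10.71,15.38
Adolescents male,11,19,male,summary,3.03,0.17,0.14,0.20,118.14,98.05,138.23,23.83,19.78,27.88,38.96,32.33,45.58,7.86,6.52,9.19
Adults,19,Inf,all,summary,49.20,0.06,0.04,0.08,695.09,502.38,887.80,140.21,101.34,179.08,14.13,10.21,18.05,2.85,2.06,3.64
Adults female,19,Inf,female,summary,25.18,0.07,0.05,0.09,429.15,311.65,546.66,86.57,62.86,110.27,17.04,12.38,21.71,3.44,2.50,4.38
Adults male,19,Inf,male,summary,24.02,0.05,0.03,0.06,260.81,184.23,337.39,52.61,37.16,68.06,10.86,7.67,14.05,2.19,1.55,2.83
11-12,11,13,all,band,1.38,0.19,0.15,0.23,61.96,49.18,74.75,12.50,9.92,15.08,44.88,35.62,54.14,9.05,7.18,10.92
13-15,13,16,all,band,2.21,0.24,0.21,0.28,125.87,107.75,144.00,25.39,21.73,29.05,56.93,48.73,65.13,11.48,9.83,13.14
16-18,16,19,all,band,2.32,0.22,0.18,0.27,120.94,97.21,144.67,24.40,19.61,29.18,52.07,41.85,62.29,10.50,8.44,12.56
19-24,19,25,all,band,5.12,0.15,0.11,0.19,178.34,133.57,223.10,35.97,26.94,45.00,34.80,26.07,43.54,7.02,5.26,8.78
25-34,25,35,all,band,8.68,0.10,0.07,0.13,205.92,150.04,261.80,41.54,30.27,52.81,23.73,17.29,30.17,4.79,3.49,6.09
35-44,35,45,all,band,8.46,0.07,0.05,0.09,138.48,93.95,183.02,27.93,18.95,36.92,16.36,11.10,21.63,3.30,2.24,4.36
45-54,45,55,all,band,9.03,0.04,0.03,0.06,93.62,63.13,124.11,18.88,12.73,25.03,10.37,6.99,13.74,2.09,1.41,2.77
55+,55,Inf,all,band,17.90,0.02,0.01,0.03,80.72,53.14,108.31,16.28,10.72,21.85,4.51,2.97,6.05,0.91,0.60,1.22
Total,11,Inf,all,total,55.11,0.14,0.13,0.14,1005.86,747.96,1263.76,202.90,150.88,254.92,18.25,13.57,22.93,3.68,2.74,4.63
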