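age_low,age_high,gender,persons_millions
11,19,all,5.91
11,19,female,2.88
11,19,male,3.03
19,Inf,all,49.20
19,Inf,female,25.18
19,Inf,male,24.02
11,13,all,1.38
13,16,all,2.21
16,19,all,2.32
19,25,all,5.12
25,35,all,8.68
35,45,all,8.46
45,55,all,9.03
55,Inf,all,17.90
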