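title,artist,class,gross_total,gross_total_lo,gross_total_hi,gross_adolescent,gross_adolescent_lo,gross_adolescent_hi,pc_adolescent,pc_adolescent_lo,pc_adolescent_hi,pc_adult,pc_adult_lo,pc_adult_hi
Timber,Pitbull ft. Ke$ha,alcohol,162.59,145.47,179.70,44.47,41.71,47.22,7.52,7.05,7.98,2.40,2.11,2.69
Trumpets,Jason Derulo,tobacco,36.80,32.31,41.30,12.27,11.46,13.09,2.07,1.94,2.21,0.50,0.42,0.57
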