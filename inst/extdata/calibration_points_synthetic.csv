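"concentration_nM","dff_pct"
10,0.0477
30,0.145
100,0.4719
300,1.1062
1000,2.4816
3000,3.7555
10000,4.6378
30000,4.8024
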