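# material bone density 1.850
# columns: E[MeV] mu_over_rho[cm2/g] mu_en_over_rho[cm2/g]
0.010  28.51    26.80
0.015  9.032    8.388
0.020  4.001    3.601
0.030  1.331    1.070
0.040  0.6655   0.4507
0.050  0.4242   0.2336
0.060  0.3148   0.1400
0.080  0.2229   0.06896
0.100  0.1855   0.04585
0.150  0.1480   0.03183
0.200  0.1309   0.03003
0.300  0.1113   0.03032
0.400  0.09908  0.03069
0.500  0.09022  0.03073
0.600  0.08332  0.03052
0.800  0.07308  0.02973
1.000  0.06566  0.02875
1.250  0.05871  0.02745
1.500  0.05346  0.02623
2.000  0.04607  0.02421
3.000  0.03745  0.02137
4.000  0.03257  0.01959
5.000  0.02946  0.01838
6.000  0.02734  0.01752
8.000  0.02467  0.01642
10.000 0.02314  0.01571
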