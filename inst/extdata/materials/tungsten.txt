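# material tungsten density 19.300
# columns: E[MeV] mu_over_rho[cm2/g] mu_en_over_rho[cm2/g]
0.010  96.91    91.00
0.015  139.3    117.3
0.020  65.73    57.60
0.030  22.73    19.91
0.040  10.67    9.240
0.050  5.949    5.050
0.060  3.713    3.070
0.080  7.810    2.879
0.100  4.438    2.100
0.150  1.581    0.9378
0.200  0.7844   0.5079
0.300  0.3238   0.2177
0.400  0.1925   0.1226
0.500  0.1378   0.08526
0.600  0.1093   0.06717
0.800  0.08066  0.04984
1.000  0.06618  0.04146
1.250  0.05577  0.03628
1.500  0.05000  0.03337
2.000  0.04433  0.03080
3.000  0.04075  0.02966
4.000  0.04038  0.02992
5.000  0.04103  0.03064
6.000  0.04210  0.03141
8.000  0.04472  0.03312
10.000 0.04747  0.03461
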