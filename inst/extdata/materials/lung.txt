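# material lung density 0.260
# columns: E[MeV] mu_over_rho[cm2/g] mu_en_over_rho[cm2/g]
0.010  5.378    4.964
0.015  1.693    1.396
0.020  0.8205   0.5638
0.030  0.3783   0.1610
0.040  0.2698   0.07192
0.050  0.2276   0.04349
0.060  0.2064   0.03258
0.080  0.1837   0.02615
0.100  0.1707   0.02544
0.150  0.1504   0.02745
0.200  0.1368   0.02942
0.300  0.1184   0.03164
0.400  0.1059   0.03247
0.500  0.09675  0.03267
0.600  0.08943  0.03252
0.800  0.07854  0.03175
1.000  0.07062  0.03073
1.250  0.06314  0.02937
1.500  0.05747  0.02806
2.000  0.04935  0.02582
3.000  0.03962  0.02258
4.000  0.03400  0.02046
5.000  0.03026  0.01896
6.000  0.02769  0.01789
8.000  0.02429  0.01642
10.000 0.02223  0.01551
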