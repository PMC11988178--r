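# material air density 0.0012
# columns: E[MeV] mu_over_rho[cm2/g] mu_en_over_rho[cm2/g]
0.010  5.120    4.742
0.015  1.614    1.334
0.020  0.7779   0.5389
0.030  0.3538   0.1537
0.040  0.2485   0.06833
0.050  0.2080   0.04098
0.060  0.1875   0.03041
0.080  0.1662   0.02407
0.100  0.1541   0.02325
0.150  0.1356   0.02496
0.200  0.1233   0.02672
0.300  0.1067   0.02872
0.400  0.09549  0.02949
0.500  0.08712  0.02966
0.600  0.08055  0.02953
0.800  0.07074  0.02882
1.000  0.06358  0.02789
1.250  0.05687  0.02666
1.500  0.05175  0.02547
2.000  0.04447  0.02345
3.000  0.03581  0.02057
4.000  0.03079  0.01870
5.000  0.02751  0.01740
6.000  0.02522  0.01647
8.000  0.02225  0.01525
10.000 0.02045  0.01450
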