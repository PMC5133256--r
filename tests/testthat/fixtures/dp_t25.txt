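-0.020664
1.195987
-1.256748
-2.676014
0.084463
-0.645178
-0.220729
1.049004
0.072216
-0.656341
0.136975
-4.314209
-1.703915
1.350474
0.389535
1.685834
-0.310140
-0.630462
-1.506006
-0.118136
-0.923448
0.010855
-2.401823
-1.373346
-0.503596
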