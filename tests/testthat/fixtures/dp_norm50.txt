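0.001230
0.298746
-0.274138
-0.890592
-0.454671
-0.991647
0.060144
1.340215
-0.492207
-0.620475
0.489842
0.356887
0.105414
-0.930468
-0.029252
0.695303
-1.344215
-0.457616
-1.901223
-1.289538
-1.841735
-0.235091
-1.267446
0.271264
0.156751
-0.186931
-2.516760
-0.538693
-0.048501
0.113309
-1.530136
-0.477753
-0.978519
-0.808837
1.060899
-0.807535
-0.032522
0.884390
-0.583600
-0.111702
0.110464
0.063782
-1.225056
0.076140
1.358823
-1.547145
0.859383
0.119354
-0.641470
2.000417
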