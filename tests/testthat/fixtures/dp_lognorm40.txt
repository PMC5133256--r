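1.579891
0.486960
1.045724
1.413422
0.892910
1.506435
0.960876
1.492345
2.370530
0.666712
1.129622
0.757309
1.079352
0.490507
0.706395
0.888947
1.714735
1.988008
0.451980
0.620776
1.474239
0.302567
0.757371
0.943299
2.125929
1.512316
0.821743
0.801600
0.860607
2.494573
0.773511
0.833428
1.235596
0.930101
0.888367
0.512507
0.993111
0.766325
2.013102
1.479720
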