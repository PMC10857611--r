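# 192Ir photon line spectrum >= 10 keV; intensities per decay
# transcription total 2.2999, rescaled by 0.999691 to 2.2992
energy_keV,intensity_per_Bq
11.200,0.00399877
61.486,0.0119963
63.000,0.0204937
65.122,0.0262919
66.831,0.0445862
71.300,0.00889725
75.900,0.0139957
136.343,0.00198939
201.311,0.00472854
205.794,0.0333897
283.267,0.00265918
295.957,0.287011
308.455,0.296908
316.506,0.828344
329.170,0.000169948
374.485,0.00725776
416.469,0.00669793
420.520,0.000689787
468.069,0.478252
484.575,0.0318802
489.060,0.00437865
588.581,0.045206
593.490,0.00041987
604.411,0.0821346
612.462,0.0533835
884.537,0.0029091
1061.480,0.000529836
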