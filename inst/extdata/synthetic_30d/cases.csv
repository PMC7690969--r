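date,region,nucleic_count,clinical_count,reported_total
2020-01-20,hubei,258,245,258
2020-01-21,hubei,330,292,330
2020-01-22,hubei,354,332,354
2020-01-23,hubei,474,405,474
2020-01-24,hubei,539,508,539
2020-01-25,hubei,660,565,660
2020-01-26,hubei,793,775,793
2020-01-27,hubei,975,874,975
2020-01-28,hubei,1160,1095,1160
2020-01-29,hubei,1438,1328,1438
2020-01-30,hubei,1667,1495,1667
2020-01-31,hubei,2033,1794,2033
2020-02-01,hubei,1638,1540,1638
2020-02-02,hubei,1293,1157,1293
2020-02-03,hubei,1185,1059,1185
2020-02-04,hubei,921,869,921
2020-02-05,hubei,780,762,780
2020-02-06,hubei,647,614,647
2020-02-07,hubei,534,485,534
2020-02-08,hubei,476,429,476
2020-02-09,hubei,402,332,402
2020-02-10,hubei,329,299,329
2020-02-11,hubei,281,257,281
2020-02-12,hubei,225,206,14440
2020-02-13,hubei,206,191,3899
2020-02-14,hubei,162,156,318
2020-02-15,hubei,141,137,278
2020-02-16,hubei,118,115,233
2020-02-17,hubei,97,92,189
2020-02-18,hubei,63,66,129
2020-01-20,other,64,0,64
2020-01-21,other,71,0,71
2020-01-22,other,93,0,93
2020-01-23,other,110,0,110
2020-01-24,other,132,0,132
2020-01-25,other,152,0,152
2020-01-26,other,181,0,181
2020-01-27,other,239,0,239
2020-01-28,other,268,0,268
2020-01-29,other,336,0,336
2020-01-30,other,413,0,413
2020-01-31,other,454,0,454
2020-02-01,other,426,0,426
2020-02-02,other,364,0,364
2020-02-03,other,349,0,349
2020-02-04,other,257,0,257
2020-02-05,other,218,0,218
2020-02-06,other,173,0,173
2020-02-07,other,144,0,144
2020-02-08,other,122,0,122
2020-02-09,other,90,0,90
2020-02-10,other,79,0,79
2020-02-11,other,63,0,63
2020-02-12,other,64,0,64
2020-02-13,other,46,0,46
2020-02-14,other,31,0,31
2020-02-15,other,31,0,31
2020-02-16,other,13,0,13
2020-02-17,other,19,0,19
2020-02-18,other,23,0,23
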