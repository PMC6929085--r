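subject,breast_lthigh_mean,breast_lthigh_sd,breast_lthigh_range,waist_lthigh_mean,waist_lthigh_sd,waist_lthigh_range
1,0.460,0.043,0.202,2.091,0.074,0.326
2,0.585,0.059,0.259,2.119,0.049,0.286
3,0.509,0.070,0.262,2.396,0.053,0.184
4,0.568,0.039,0.190,1.705,0.482,1.224
5,0.271,0.054,0.225,2.025,0.065,0.268
6,0.089,0.039,0.190,1.660,0.107,0.431
7,0.730,0.064,0.222,2.306,0.101,0.332
8,0.516,0.033,0.137,2.068,0.038,0.157
9,0.594,0.078,0.404,1.990,0.120,0.524
10,0.394,0.063,0.268,2.092,0.115,0.419
11,0.946,0.109,0.365,2.737,0.110,0.389
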