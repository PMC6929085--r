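posture,correct,total
1,9351,9384
2,8729,9192
3,8805,9459
4,6278,8746
5,8792,8792
6,7414,9131
7,8654,8663
8,9386,9499
9,8630,8630
10,6937,8596
11,6171,8252
12,8183,8772
13,6260,8581
14,6043,8563
15,9202,9202
16,9021,9021
17,8788,8788
18,6097,8505
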