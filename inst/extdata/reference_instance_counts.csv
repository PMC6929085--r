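posture,correct,total
1,76,77
2,72,77
3,67,77
4,56,63
5,77,77
6,60,77
7,77,77
8,75,77
9,77,77
10,63,63
11,55,59
12,71,77
13,54,60
14,55,56
15,77,77
16,77,77
17,77,77
18,56,56
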