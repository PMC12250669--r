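time_min,control,treated
0,1003.515,1003.735
5,826.035,964.825
10,679.687,925.125
15,576.056,879.669
20,485.653,844.931
25,425.679,810.37
30,384.002,781.566
35,348.613,744.562
40,310.984,718.493
45,285.337,692.049
50,261.308,664.45
55,244.236,653.439
60,247.615,628.248
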