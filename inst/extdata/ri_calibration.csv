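rt,ri
7.47,655.56
8.2,671.46
8.7,682.35
8.94,687.58
9.55,700.94
10.32,718.97
10.77,729.51
10.79,729.98
11.12,737.7
12.1,760.66
13.01,781.97
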