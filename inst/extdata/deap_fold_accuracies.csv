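fold,arousal,valence,quaternary
1,95.36,94.23,92.83
2,94.95,94.61,93.20
3,95.31,94.88,92.97
4,94.90,94.60,93.40
5,95.46,94.57,92.89
6,94.83,94.78,92.54
7,95.44,94.69,93.19
8,95.34,94.64,92.92
9,95.23,94.30,93.22
10,95.23,94.61,92.98
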