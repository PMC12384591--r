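index,name
1,Fp1
2,AF3
3,F3
4,F7
5,FC5
6,FC1
7,C3
8,T7
9,CP5
10,CP1
11,P3
12,P7
13,PO3
14,O1
15,Oz
16,Pz
17,Fp2
18,AF4
19,Fz
20,F4
21,F8
22,FC6
23,FC2
24,Cz
25,C4
26,T8
27,CP6
28,CP2
29,P4
30,P8
31,PO4
32,O2
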