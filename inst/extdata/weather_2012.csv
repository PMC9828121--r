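day,day_of_year,mean_temp_C,max_temp_C,foraging_hours
1,208,20.1,26.855,2.8
2,209,21.5,27.176,14
3,210,22.109,30.372,2.8
4,211,21.483,28.532,2.8
5,212,21.496,29.79,14
6,213,24.717,30.379,14
7,214,22.766,30.173,14
8,215,23.707,31.684,14
9,216,22.919,30.207,14
10,217,21.05,28.413,14
11,218,21.337,27.474,14
12,219,23.131,30.686,14
13,220,23.108,30.343,14
14,221,24.036,32.346,2.8
15,222,19.893,28.283,14
16,223,20.099,28.359,14
17,224,21.754,28.53,14
18,225,21.018,26.987,14
19,226,19.442,26.537,14
20,227,19.673,27.146,14
21,228,17.072,25.278,2.8
22,229,18.953,25.021,2.8
23,230,21.06,27.054,14
24,231,22.151,29.183,2.8
25,232,23.987,32.23,14
26,233,21.263,29.092,14
27,234,18.418,26.185,14
28,235,16.901,24.693,14
29,236,19.402,27.787,14
30,237,20.434,26.183,14
31,238,18.464,24.07,2.8
32,239,18.915,25.76,14
33,240,19.016,25.646,14
34,241,18.617,26.796,14
35,242,19.966,25.943,2.8
36,243,20.874,28.471,14
37,244,21.518,29.509,14
38,245,19.379,25.158,14
39,246,21.96,29.145,2.8
40,247,21.962,29.256,14
41,248,24.361,31.573,2.8
42,249,23.89,29.793,14
43,250,21.976,29.14,14
44,251,21.278,29.145,2.8
45,252,20.4,28.402,14
46,253,16.806,23.975,14
47,254,16.587,24.013,14
48,255,20.737,28.949,2.8
49,256,20.291,27.986,2.8
50,257,18.731,26.74,2.8
51,258,19.301,25.114,14
52,259,22.38,30.338,2.8
53,260,19.958,27.568,14
54,261,21.366,27.17,2.8
55,262,21.612,27.277,14
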