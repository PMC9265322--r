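corridor,level,length_km
1,1,455.16
2,1,436.14
3,1,471.36
4,1,18.12
5,1,516.24
6,1,22.38
7,1,88.92
8,1,29.22
9,1,13.86
10,1,333.30
11,2,455.11
12,2,42.60
13,2,78.30
14,2,81.48
15,2,61.98
16,2,26.64
17,2,38.22
18,2,51.06
19,2,119.64
20,2,17.10
21,2,43.92
22,2,113.34
23,2,38.04
24,2,51.24
25,2,23.46
26,2,84.30
27,2,10.66
28,2,10.08
29,2,55.62
30,3,43.47
31,3,57.28
32,3,89.31
33,3,96.03
34,3,41.49
35,3,67.94
36,3,65.82
37,3,154.74
38,3,99.24
39,3,172.74
40,3,38.46
41,3,81.90
42,3,107.94
43,3,96.54
44,3,90.84
45,3,48.90
46,3,44.28
47,3,75.96
48,3,31.68
49,3,61.56
50,3,32.46
51,3,73.86
52,3,151.98
53,3,184.50
54,3,107.76
55,3,178.98
56,3,529.02
57,3,88.56
58,3,246.24
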