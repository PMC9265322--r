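src,dst,gravity
1,2,5.99
1,3,3.75
1,4,3.06
1,5,4.74
1,6,2.24
1,7,2.70
1,8,2.45
1,9,4.15
1,10,1.90
1,11,1.61
2,3,101.81
2,4,1.44
2,5,2.00
2,6,1.10
2,7,1.31
2,8,1.20
2,9,1.88
2,10,0.99
2,11,0.87
3,4,1.11
3,5,1.50
3,6,0.86
3,7,1.01
3,8,0.93
3,9,1.44
3,10,0.78
3,11,0.70
4,5,1.67
4,6,0.95
4,7,1.13
4,8,1.04
4,9,1.60
4,10,0.87
4,11,0.78
5,6,18.59
5,7,61.18
5,8,35.44
5,9,265.43
5,10,15.55
5,11,9.44
6,7,11.52
6,8,147.38
6,9,25.24
6,10,109.43
6,11,49.75
7,8,22.85
7,9,253.24
7,10,11.08
7,11,6.99
8,9,64.39
8,10,113.97
8,11,33.46
9,10,23.50
9,11,13.17
10,11,116.81
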