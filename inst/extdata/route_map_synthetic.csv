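id,kind,x_m,y_m
1,hand,1.60,0.45
2,hand,0.95,1.20
3,hand,2.05,1.85
4,hand,1.30,2.60
5,hand,2.05,3.476
6,hand,1.15,4.10
7,hand,1.90,4.90
8,hand,1.05,5.60
9,hand,2.10,6.35
10,hand,1.25,7.05
11,hand,1.95,7.80
12,hand,1.10,8.55
13,hand,2.00,9.30
14,hand,1.20,10.00
15,hand,1.90,10.75
16,hand,1.05,11.45
17,hand,2.05,12.20
18,hand,1.25,12.95
19,hand,1.85,13.70
20,hand,1.50,14.60
21,foot,1.05,0.15
22,foot,2.20,0.70
23,foot,0.80,1.55
24,foot,2.30,2.10
25,foot,0.95,2.90
26,foot,2.30,3.85
27,foot,0.85,4.45
28,foot,2.25,5.15
29,foot,1.00,5.95
30,foot,2.20,6.70
31,foot,1.10,7.40
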