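channel,hemisphere,region,roi
1,R,PMC,R_PMC
2,R,PMC,R_PMC
3,R,PFC,R_PFC
4,R,PFC,R_PFC
5,R,PFC,R_PFC
6,R,PFC,R_PFC
7,R,PFC,R_PFC
8,L,PFC,L_PFC
9,L,PFC,L_PFC
10,L,PFC,L_PFC
11,L,PFC,L_PFC
12,L,PFC,L_PFC
13,L,PMC,L_PMC
14,L,PMC,L_PMC
15,R,S1,R_S1
16,R,M1,R_M1
17,R,PFC,R_PFC
18,R,PFC,R_PFC
19,R,PFC,R_PFC
20,L,PFC,L_PFC
21,R,PFC,R_PFC
22,L,PFC,L_PFC
23,L,PFC,L_PFC
24,L,PFC,L_PFC
25,L,PFC,L_PFC
26,L,PMC,L_PMC
27,L,PMC,L_PMC
28,R,PMC,R_PMC
29,R,PMC,R_PMC
30,L,S1,L_S1
31,L,M1,L_M1
32,L,S1,L_S1
33,L,S1,L_S1
34,R,S1,R_S1
35,R,S1,R_S1
36,R,V,R_V
37,R,V,R_V
38,R,V,R_V
39,L,V,L_V
40,L,V,L_V
41,L,V,L_V
42,R,M1,R_M1
43,L,PMC,L_PMC
44,L,M1,L_M1
45,R,PMC,R_PMC
46,R,V,R_V
47,L,V,L_V
48,L,V,L_V
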