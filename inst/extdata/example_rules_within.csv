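no,antecedent,consequent,support_pct,confidence_pct,lift
1,Q44,Q61,19.89,97.27,4.71
2,K20;K80,K29,0.33,96.77,1.81
3,Q61,Q44,19.89,96.40,4.71
4,I66,I63,5.94,96.05,1.46
5,I25;I66,I63,1.73,94.69,1.44
6,I65,I63,5.01,92.64,1.41
7,K20,K29,4.15,92.25,1.73
8,R13,R47,12.15,90.91,5.77
9,I61;I70,I10,0.13,89.04,1.24
10,G80,G40,1.35,86.54,3.94
11,I61;I69,I10,1.11,86.32,1.20
12,I25;I61,I10,0.64,86.14,1.20
13,K21,K29,4.15,85.71,1.61
14,I20;I69,I10,0.39,84.78,1.18
15,I69;I70,I10,0.20,84.48,1.18
16,I25;I69,I10,1.10,84.19,1.17
17,I25;I71,I10,0.17,83.84,1.17
18,I20;I66,I10,0.54,83.44,1.16
19,I61;I80,I10,0.12,83.33,1.16
20,I20;I61,I10,0.22,82.71,1.15
21,I61;I63,I10,2.20,82.41,1.15
22,J03;J04,J18,0.48,82.22,1.47
23,I61,I10,3.99,82.09,1.15
24,I61;I66,I10,0.21,82.03,1.14
25,I50;I65,I10,0.21,81.54,1.14
26,I63;I71,I10,0.24,81.25,1.13
27,I10;I70,I63,3.40,81.08,1.23
28,I70,I63,5.18,81.05,1.23
29,I25;I66,I10,1.48,80.97,1.13
30,J21,J18,2.08,80.80,1.44
31,K65;K70,K74,0.55,80.65,5.85
32,I20;I65,I10,0.67,80.43,1.12
33,I66;I69,I10,0.47,80.34,1.12
34,I71,I10,0.49,80.00,1.12
35,I25;I70,I63,1.77,79.53,1.21
36,I69,I10,4.05,79.39,1.11
37,K26,K29,3.91,79.06,1.48
38,I65;I69,I10,0.28,78.77,1.10
39,I63;I69,I10,3.04,78.47,1.09
40,I25;I65,I10,1.52,78.17,1.09
41,I65;I66,I10,1.29,77.95,1.09
42,J03;J21,J18,0.40,77.50,1.38
43,H04;H40,H25,0.72,77.42,2.04
44,I95,I63,0.13,77.38,1.17
45,C65,C64,0.47,77.19,27.80
46,R47,R13,12.15,77.18,5.77
47,J04,J18,2.14,76.38,1.36
48,I50;I70,I10,0.34,76.15,1.06
49,I20;I70,I63,0.71,76.14,1.16
50,I05,I48,0.43,75.89,8.25
51,I20;I70,I10,0.70,75.49,1.05
52,I66;I70,I10,0.45,75.17,1.05
53,I20;I63,I10,7.95,75.10,1.05
54,B91,B18,0.31,75.00,2.19
55,H72,H66,0.72,75.00,16.17
56,I48;I66,I10,0.27,75.00,1.05
57,I50;I69,I10,0.35,74.89,1.04
58,J03;J20,J18,1.93,74.44,1.33
59,I50;I66,I10,0.19,74.42,1.04
60,I63;I66,I10,4.42,74.34,1.04
61,I21,I25,4.70,74.21,1.79
62,I66,I10,4.58,74.08,1.03
63,I69;I80,I10,0.12,74.07,1.03
64,I48;I70,I63,0.32,74.07,1.12
65,J03,J18,9.44,74.06,1.32
66,G97,G91,1.71,74.03,8.32
67,I25;I70,I10,1.65,74.00,1.03
68,I63,I10,48.68,73.86,1.03
69,D06,D25,3.04,73.38,3.53
70,I00,I10,0.12,73.17,1.02
71,I63;I65,I10,3.66,72.95,1.02
72,I25;I63,I10,16.95,72.90,1.02
73,I65,I10,3.94,72.78,1.02
74,I48;I70,I10,0.32,72.22,1.01
75,K44,K29,1.68,72.21,1.35
76,J04;J20,J18,0.53,72.17,1.29
77,H04,H25,5.09,71.91,1.89
78,S93,S82,1.61,71.70,4.85
79,S06;S32,S22,2.76,70.65,2.08
80,E02;E79,E11,0.20,70.27,1.04
81,F84,F79,18.96,70.18,2.64
82,C19,C18,0.15,70.00,9.69
83,C19,C20,0.15,70.00,9.78
84,I10;I74,I63,0.24,70.00,1.06
85,E02;E77,E11,0.17,69.70,1.03
86,F80,F84,24.88,69.08,2.56
87,K65;K80,K74,0.49,68.75,4.99
88,I25;I80,I63,0.27,68.00,1.03
89,I10,I63,48.68,67.92,1.03
90,K70,K74,2.57,67.64,4.91
91,S02;S32,S22,2.12,66.67,1.96
92,J03;J40,J18,0.77,65.57,1.17
93,K25,K29,2.88,64.68,1.21
94,K58,K29,0.71,64.65,1.21
95,K65,K74,2.98,62.41,4.53
96,K57,K29,1.25,62.15,1.16
97,J20,J18,6.98,62.11,1.11
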