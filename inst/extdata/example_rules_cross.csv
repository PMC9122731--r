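no,antecedent,consequent,support_pct,confidence_pct,lift
1,E11;N18,I10,1.08,83.61,1.98
2,G20,I63,1.01,83.55,2.16
3,E11;G45,I63,1.05,83.18,2.15
4,G45,I63,3.80,78.97,2.17
5,G81,I10,1.08,73.21,1.77
6,N18,I10,2.90,70.28,1.81
7,E11;G45,I10,1.05,70.22,1.35
8,M50,I63,1.74,68.27,1.91
9,M47,I63,2.15,66.25,1.85
10,E14,I10,2.04,62.74,1.61
11,E11;J18,I63,1.01,62.13,1.57
12,E11,I10,11.73,61.49,1.58
13,E02,I63,1.02,60.79,1.49
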