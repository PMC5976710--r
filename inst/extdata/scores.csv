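treatment,tumor_type,segment,reg_quality_r1,reg_quality_r2,position_r1,position_r2,clinical_indication_r1,clinical_indication_r2,confidence_r1,confidence_r2
1,HCC,6,5,4,5,5,5,5,5,5
2,HCC,2,3,3,3,3,3,3,4,5
2,HCC,8,NA,NA,4,3,4,4,4,5
3,HCC,4,4,4,4,5,5,5,5,4
4,HCC,2,3,4,4,5,5,5,5,5
5,MET,7,5,5,4,5,4,5,5,5
6,HCC,2,5,5,5,5,5,5,5,5
7,HCC,4,4,5,5,4,5,5,5,5
8,HCC,5,5,4,4,5,4,5,5,4
9,HCC,8,5,5,5,5,5,5,5,5
10,HCC,5,4,5,5,4,5,5,5,5
11,MET,8,5,4,5,4,5,5,5,5
12,HCC,6,5,4,5,5,4,4,4,5
13,MET,4,4,5,4,5,5,5,5,4
14,HCC,4,2,3,4,4,4,4,4,3
15,MET,2,3,3,3,4,4,3,4,4
16,HCC,8,5,4,4,5,4,4,4,4
16,HCC,2,NA,NA,3,4,3,3,3,4
17,HCC,3,5,5,4,5,4,4,4,5
18,HCC,5,5,5,5,5,5,5,5,5
18,HCC,4,NA,NA,5,5,5,5,5,5
19,HCC,8,4,5,4,5,5,4,5,5
20,HCC,8,5,5,5,5,5,5,5,5
20,HCC,4,NA,NA,5,5,5,5,5,5
21,HCC,5,5,4,4,4,3,3,3,4
22,HCC,6,4,4,5,4,5,5,5,4
23,HCC,2,5,4,4,5,4,5,4,4
24,HCC,4,4,5,5,5,5,5,5,4
24,HCC,3,NA,NA,5,4,5,5,5,5
25,MET,2,5,4,5,5,5,5,5,4
26,HCC,2,3,4,5,4,5,4,5,5
27,HCC,5,5,5,4,5,4,5,4,5
27,HCC,2,NA,NA,4,5,4,5,4,5
28,MET,7,5,5,4,4,4,4,4,4
28,MET,8,NA,NA,5,4,5,5,5,5
29,MET,8,5,5,5,5,5,5,5,5
29,MET,2,NA,NA,5,5,5,5,5,5
30,MET,2,4,5,5,5,5,5,5,5
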