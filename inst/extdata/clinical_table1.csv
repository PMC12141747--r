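Patient,Handedness,Duration,Onset,MRC_right,MRC_left,ALSFRS_r,ECAS_specific,ECAS_total,Form
1,Right,60,LL (left),8,6,37,41,64,PLMN
2,Left,36,B,9,9,34,73,99,PLMN
3,Right,18,LL,9,9,41,90,124,PUMN
4,Right,45,LL (right),8,6,36,79,108,Classical
5,Right,10,UL (left),10,4,44,62,91,PUMN
6,Left,15,LL (left),10,10,44,82,114,PUMN
7,Right,14,UL (right),8,8,43,78,107,Classical
8,Left,36,UL (right),10,10,40,80,114,PLMN
9,Right,15,LL (left),9,9,42,,,PLMN
10,Right,8,UL (right),7,8,36,67,102,PLMN
11,Right,8,B,9,9,34,44,66,Classical
12,Right,8,LL (right),8,9,43,83,118,PLMN
13,Right,76,LL (left),10,10,41,63,95,PUMN
14,Right,37,LL (right),8,10,34,83,112,PLMN
15,Right,22,UL (left),10,10,38,89,123,PUMN
16,Right,11,B,10,10,43,69,94,PUMN
17,Right,6,B,10,10,47,81,114,Classical
18,Right,3,LL (left),10,10,40,92,122,PLMN
19,Right,43,B,9,10,39,64,91,PUMN
20,Right,31,UL (right),6,8,35,79,109,Classical
21,Right,20,UL (left),10,9,47,77,111,PLMN
22,Right,9,LL (left),10,10,40,88,123,PLMN
23,Right,7,UL (left),10,10,43,80,109,PLMN
24,Right,9,UL (right),5,8,35,77,109,PLMN
25,Right,8,LL (right),8,10,40,89,120,PUMN
26,Right,7,LL (left),8,9,38,87,118,PUMN
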