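case_id,sex,age,side,pathology,grade,lobe,r2
8,F,34,R,GBM,4,frontal,0.7
20,M,56,R,GBM,4,frontal,0.75
22,M,22,L,GBM,4,frontal,0.7
30,M,20,R,oligodendroglioma,2,frontal,0.76
31,M,54,R,GBM,4,frontal,0.74
32,F,34,L,oligodendroglioma,2,frontal,0.78
36,M,30,R,GBM,4,frontal,0.71
40,M,23,R,astrocytoma,3,frontal,0.7
41,F,58,R,GBM,4,frontal,0.63
42,M,32,R,astrocytoma,2,frontal,0.66
43,M,35,L,astrocytoma,2,frontal,0.61
44,F,64,R,oligodendroglioma,2,frontal,0.69
48,F,36,R,GBM,4,frontal,0.72
50,F,37,L,oligodendroglioma,2,frontal,0.74
51,F,48,L,astrocytoma,3,frontal,0.7
52,M,60,R,GBM,4,frontal,0.72
53,M,35,L,oligodendroglioma,3,frontal,0.75
55,M,62,R,GBM,4,frontal,0.71
57,M,80,R,GBM,4,frontal,0.7
58,M,60,R,GBM,4,frontal,0.61
59,F,34,L,astrocytoma,2,frontal,0.75
60,F,68,R,GBM,4,frontal,0.66
11,M,38,R,oligodendroglioma,3,parietal,0.68
27,M,35,L,oligodendroglioma,3,parietal,0.71
38,F,73,L,GBM,4,parietal,0.76
39,M,56,R,GBM,4,parietal,0.64
54,M,76,R,GBM,4,parietal,0.66
5,F,42,L,GBM,4,temporal,0.69
35,F,23,R,astrocytoma,2,temporal,0.76
45,M,53,R,astrocytoma,3,temporal,0.7
46,F,61,R,GBM,4,temporal,0.7
49,M,33,L,GBM,4,temporal,0.73
56,F,37,L,oligodendroglioma,2,temporal,0.58
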