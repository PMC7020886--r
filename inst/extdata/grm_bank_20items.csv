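item_id,model,n_categories,a,b1,b2,b3,b4
1,GRM,4,0.942,-0.609,2.211,4.352,
2,GRM,4,0.902,-1.761,0.812,3.387,
3,GRM,4,1.120,-0.388,1.833,3.388,
4,GRM,4,0.868,-0.500,2.318,4.240,
5,GRM,4,0.851,-0.421,2.156,3.650,
6,GRM,4,0.995,-1.154,1.604,4.030,
7,GRM,4,1.196,0.226,2.584,3.986,
8,GRM,4,1.016,-0.189,2.112,4.123,
9,GRM,4,1.013,0.612,3.268,5.360,
10,GRM,4,1.509,0.205,1.928,3.406,
84,GRM,5,1.048,-0.612,1.080,3.083,4.671
85,GRM,5,0.899,-2.130,-0.216,1.692,3.833
86,GRM,5,1.186,-0.978,0.625,1.978,3.227
87,GRM,5,1.024,-1.086,0.600,2.045,3.271
88,GRM,5,1.156,-1.269,0.398,1.868,2.996
89,GRM,5,1.275,-0.796,0.533,1.880,3.195
90,GRM,5,1.513,-0.276,0.958,1.931,3.051
91,GRM,5,1.170,-0.445,0.884,2.177,3.257
92,GRM,5,1.197,0.075,1.578,2.886,4.019
93,GRM,5,0.904,-0.202,1.561,3.049,4.020
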