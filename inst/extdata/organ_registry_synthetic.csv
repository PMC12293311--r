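id,name,density,weight_class,H,C,N,O,Na,Mg,P,S,Cl,K,Ca,Fe,I
1,skin,1.09,weighted,0.100,0.204,0.042,0.645,0.002,0,0.001,0.002,0.003,0.001,0,0,0
2,muscle,1.05,remainder,0.102,0.143,0.034,0.710,0.001,0,0.002,0.003,0.001,0.004,0,0,0
3,skeleton,1.92,unscored,0.034,0.155,0.042,0.435,0.001,0.002,0.103,0.003,0,0,0.225,0,0
4,red_marrow,1.03,weighted,0.105,0.414,0.034,0.441,0,0,0.001,0.002,0.002,0,0,0.001,0
5,bone_surface,1.03,weighted,0.102,0.143,0.034,0.708,0.002,0,0.003,0.003,0.002,0.003,0,0,0
6,brain,1.04,weighted,0.107,0.145,0.022,0.712,0.002,0,0.004,0.002,0.003,0.003,0,0,0
7,eye_lenses,1.07,unscored,0.096,0.195,0.057,0.646,0.001,0,0.001,0.003,0.001,0,0,0,0
8,salivary_glands,1.03,weighted,0.102,0.143,0.034,0.708,0.002,0,0.003,0.003,0.002,0.003,0,0,0
9,thyroid,1.05,weighted,0.104,0.119,0.024,0.745,0.002,0,0.001,0.001,0.002,0.001,0,0,0.001
10,oesophagus,1.03,weighted,0.102,0.143,0.034,0.708,0.002,0,0.003,0.003,0.002,0.003,0,0,0
11,lungs,0.26,weighted,0.103,0.105,0.031,0.749,0.002,0,0.002,0.003,0.003,0.002,0,0,0
12,heart,1.05,remainder,0.102,0.110,0.033,0.745,0.001,0,0.001,0.002,0.002,0.003,0,0.001,0
13,liver,1.06,weighted,0.102,0.110,0.033,0.745,0.001,0,0.001,0.002,0.002,0.003,0,0.001,0
14,stomach,1.04,weighted,0.102,0.143,0.034,0.708,0.002,0,0.003,0.003,0.002,0.003,0,0,0
15,spleen,1.06,remainder,0.102,0.110,0.033,0.745,0.001,0,0.001,0.002,0.002,0.003,0,0.001,0
16,kidneys,1.05,remainder,0.102,0.110,0.033,0.745,0.001,0,0.001,0.002,0.002,0.003,0,0.001,0
17,pancreas,1.04,remainder,0.102,0.143,0.034,0.708,0.002,0,0.003,0.003,0.002,0.003,0,0,0
18,adrenals,1.03,remainder,0.102,0.143,0.034,0.708,0.002,0,0.003,0.003,0.002,0.003,0,0,0
19,small_intestine,1.03,remainder,0.102,0.143,0.034,0.708,0.002,0,0.003,0.003,0.002,0.003,0,0,0
20,colon_upper,1.03,weighted,0.102,0.143,0.034,0.708,0.002,0,0.003,0.003,0.002,0.003,0,0,0
21,colon_lower,1.03,weighted,0.102,0.143,0.034,0.708,0.002,0,0.003,0.003,0.002,0.003,0,0,0
22,bladder,1.04,weighted,0.102,0.143,0.034,0.708,0.002,0,0.003,0.003,0.002,0.003,0,0,0
23,gonads,1.04,weighted,0.102,0.143,0.034,0.708,0.002,0,0.003,0.003,0.002,0.003,0,0,0
24,breast,1.02,weighted,0.106,0.332,0.030,0.527,0.001,0,0.001,0.002,0.001,0,0,0,0
25,thymus,1.03,remainder,0.102,0.143,0.034,0.708,0.002,0,0.003,0.003,0.002,0.003,0,0,0
26,gall_bladder,1.03,remainder,0.102,0.143,0.034,0.708,0.002,0,0.003,0.003,0.002,0.003,0,0,0
27,lymph_nodes,1.03,remainder,0.102,0.143,0.034,0.708,0.002,0,0.003,0.003,0.002,0.003,0,0,0
28,prostate,1.04,remainder,0.102,0.143,0.034,0.708,0.002,0,0.003,0.003,0.002,0.003,0,0,0
29,spinal_cord,1.04,unscored,0.107,0.145,0.022,0.712,0.002,0,0.004,0.002,0.003,0.003,0,0,0
30,adipose,0.95,unscored,0.114,0.598,0.007,0.278,0.001,0,0,0.001,0.001,0,0,0,0
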