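element,energy_MeV,mu_rho,muen_rho
H,0.01,0.388834,0.0133745
H,0.015,0.377402,0.012002
H,0.02,0.369845,0.0139478
H,0.03,0.357132,0.0187447
H,0.04,0.345824,0.0231905
H,0.05,0.335495,0.0271061
H,0.06,0.32599,0.0305379
H,0.08,0.309051,0.0362046
H,0.1,0.294388,0.0406294
H,0.15,0.265026,0.048119
H,0.2,0.242847,0.0525408
H,0.3,0.211163,0.0569412
H,0.4,0.189195,0.0585799
H,0.5,0.172758,0.0589738
H,0.6,0.159812,0.0587334
H,0.8,0.140373,0.0573649
H,1,0.126183,0.0555259
H,1.25,0.112807,0.0530845
C,0.01,2.16693,1.97788
C,0.015,0.711398,0.527405
C,0.02,0.389158,0.20995
C,0.03,0.233503,0.0631122
C,0.04,0.195027,0.0325684
C,0.05,0.178983,0.0236974
C,0.06,0.169674,0.0209026
C,0.08,0.15777,0.0203811
C,0.1,0.14927,0.0214929
C,0.15,0.133724,0.0245034
C,0.2,0.122389,0.0265628
C,0.3,0.106357,0.0287003
C,0.4,0.0952781,0.0295082
C,0.5,0.0869956,0.0297009
C,0.6,0.0804744,0.0295774
C,0.8,0.0706844,0.0288866
C,1,0.0635385,0.02796
C,1.25,0.056803,0.0267304
N,0.01,3.63303,3.4439
N,0.015,1.09923,0.915164
N,0.02,0.54016,0.360878
N,0.03,0.273497,0.103035
N,0.04,0.210637,0.0481108
N,0.05,0.186527,0.0311764
N,0.06,0.173852,0.0250187
N,0.08,0.159434,0.0219883
N,0.1,0.150101,0.0222708
N,0.15,0.133984,0.024717
N,0.2,0.122519,0.026653
N,0.3,0.106422,0.0287332
N,0.4,0.0953259,0.0295287
N,0.5,0.0870357,0.0297171
N,0.6,0.0805101,0.0295919
N,0.8,0.0707146,0.0288994
N,1,0.0635653,0.027972
N,1.25,0.0568269,0.0267417
O,0.01,5.75971,5.57046
O,0.015,1.66181,1.47764
O,0.02,0.759192,0.579809
O,0.03,0.331504,0.160946
O,0.04,0.233273,0.0706557
O,0.05,0.197463,0.0420248
O,0.06,0.179906,0.0309886
O,0.08,0.161842,0.0243189
O,0.1,0.151301,0.0233984
O,0.15,0.134354,0.0250258
O,0.2,0.122703,0.0267828
O,0.3,0.106513,0.0287797
O,0.4,0.0953914,0.0295571
O,0.5,0.0870903,0.0297395
O,0.6,0.0805585,0.0296117
O,0.8,0.0707556,0.0289169
O,1,0.0636017,0.0279883
O,1.25,0.0568591,0.026757
Na,0.01,16.9477,16.7666
Na,0.015,4.61503,4.4388
Na,0.02,1.90381,1.73217
Na,0.03,0.628617,0.465414
Na,0.04,0.344422,0.188817
Na,0.05,0.247247,0.0985122
Na,0.06,0.204207,0.0617115
Na,0.08,0.167341,0.0357484
Na,0.1,0.150778,0.0283913
Na,0.15,0.130148,0.0255341
Na,0.2,0.11803,0.0262458
Na,0.3,0.102083,0.0277021
Na,0.4,0.0913415,0.0283461
Na,0.5,0.0833654,0.0284877
Na,0.6,0.0771015,0.0283516
Na,0.8,0.0677111,0.0276765
Na,1,0.0608622,0.0267846
Na,1.25,0.0544088,0.0256047
Mg,0.01,23.8511,23.6642
Mg,0.015,6.44517,6.26332
Mg,0.02,2.61958,2.44246
Mg,0.03,0.821923,0.653516
Mg,0.04,0.422842,0.262275
Mg,0.05,0.287568,0.13409
Mg,0.06,0.228555,0.0815163
Mg,0.08,0.17962,0.0438309
Mg,0.1,0.158925,0.0326359
Mg,0.15,0.135181,0.0272316
Mg,0.2,0.122137,0.0274264
Mg,0.3,0.105429,0.0286763
Mg,0.4,0.0942895,0.0292854
Mg,0.5,0.0860407,0.0294131
Mg,0.6,0.0795694,0.029265
Mg,0.8,0.0698738,0.0285627
Mg,1,0.0628046,0.0276404
Mg,1.25,0.0561445,0.026422
P,0.01,52.0084,51.8251
P,0.015,13.8901,13.7117
P,0.02,5.5152,5.34147
P,0.03,1.58534,1.42015
P,0.04,0.718012,0.560518
P,0.05,0.42793,0.27739
P,0.06,0.304393,0.160168
P,0.08,0.207403,0.0742126
P,0.1,0.170901,0.047028
P,0.15,0.136566,0.0306823
P,0.2,0.121346,0.0284475
P,0.3,0.10382,0.0285364
P,0.4,0.0926442,0.0288841
P,0.5,0.0844707,0.0289268
P,0.6,0.0780887,0.028747
P,0.8,0.068553,0.0280324
P,1,0.0616106,0.0271193
P,1.25,0.0550739,0.0259202
S,0.01,67.564,67.3752
S,0.015,18.0086,17.8248
S,0.02,7.12156,6.94252
S,0.03,2.01408,1.84385
S,0.04,0.887971,0.725668
S,0.05,0.5122,0.357063
S,0.06,0.352843,0.204214
S,0.08,0.228976,0.0917187
S,0.1,0.183449,0.0557943
S,0.15,0.142675,0.033558
S,0.2,0.125806,0.0300708
S,0.3,0.10719,0.0296074
S,0.4,0.0955507,0.0298438
S,0.5,0.0870873,0.0298474
S,0.6,0.0804937,0.0296453
S,0.8,0.0706542,0.0288964
S,1,0.0634957,0.0279512
S,1.25,0.0567574,0.0267135
Cl,0.01,80.7111,80.5296
Cl,0.015,21.4806,21.3039
Cl,0.02,8.46854,8.29651
Cl,0.03,2.36525,2.20168
Cl,0.04,1.02059,0.864632
Cl,0.05,0.57266,0.423589
Cl,0.06,0.383306,0.240489
Cl,0.08,0.237249,0.10536
Cl,0.1,0.184562,0.0618988
Cl,0.15,0.139287,0.0344374
Cl,0.2,0.121739,0.0297479
Cl,0.3,0.103224,0.0286752
Cl,0.4,0.0919021,0.0287646
Cl,0.5,0.0837241,0.0287225
Cl,0.6,0.0773693,0.0285093
Cl,0.8,0.0679004,0.0277755
Cl,1,0.0610171,0.0268626
Cl,1.25,0.05454,0.0256709
K,0.01,121.974,121.79
K,0.015,32.3963,32.2173
K,0.02,12.7187,12.5443
K,0.03,3.49107,3.32531
K,0.04,1.46012,1.30208
K,0.05,0.785164,0.634101
K,0.06,0.501077,0.356351
K,0.08,0.284266,0.150613
K,0.1,0.208118,0.0838151
K,0.15,0.146727,0.0404757
K,0.2,0.125537,0.0323167
K,0.3,0.105178,0.0296328
K,0.4,0.093354,0.0293725
K,0.5,0.0849506,0.0292139
K,0.6,0.0784625,0.0289495
K,0.8,0.0688309,0.0281697
K,1,0.0618437,0.0272327
K,1.25,0.0552743,0.0260194
Ca,0.01,150.617,150.429
Ca,0.015,39.976,39.7922
Ca,0.02,15.6718,15.4928
Ca,0.03,4.27558,4.10537
Ca,0.04,1.7682,1.60591
Ca,0.05,0.935573,0.780448
Ca,0.06,0.585651,0.437033
Ca,0.08,0.319584,0.182337
Ca,0.1,0.227025,0.0993799
Ca,0.15,0.154193,0.0450849
Ca,0.2,0.130284,0.034556
Ca,0.3,0.108369,0.0307921
Ca,0.4,0.0960056,0.0303035
Ca,0.5,0.087303,0.0300674
Ca,0.6,0.0806098,0.0297653
Ca,0.8,0.0706965,0.0289418
Ca,1,0.0635138,0.027972
Ca,1.25,0.0567641,0.0267225
Fe,0.01,361.075,360.899
Fe,0.015,95.632,95.4606
Fe,0.02,37.327,37.16
Fe,0.03,9.99458,9.83577
Fe,0.04,3.9872,3.83579
Fe,0.05,1.99719,1.85246
Fe,0.06,1.16466,1.02601
Fe,0.08,0.538807,0.410761
Fe,0.1,0.327555,0.208466
Fe,0.15,0.174472,0.0726777
Fe,0.2,0.133466,0.0441557
Fe,0.3,0.104256,0.0318797
Fe,0.4,0.0907965,0.0294988
Fe,0.5,0.0820406,0.0286419
Fe,0.6,0.0755306,0.0280945
Fe,0.8,0.0660836,0.0271279
Fe,1,0.0593169,0.0261576
Fe,1.25,0.0529881,0.0249603
I,0.01,4204.35,4204.19
I,0.015,1112.15,1112
I,0.02,432.972,432.822
I,0.03,114.629,114.486
I,0.04,44.7035,44.5677
I,0.05,21.5731,21.4433
I,0.06,11.9227,11.7983
I,0.08,4.71729,4.60243
I,0.1,2.33032,2.22349
I,0.15,0.695153,0.60384
I,0.2,0.329379,0.249264
I,0.3,0.148975,0.0840502
I,0.4,0.103032,0.0480453
I,0.5,0.0839752,0.0360744
I,0.6,0.0734627,0.0309107
I,0.8,0.0615016,0.0265569
I,1,0.0542784,0.0245332
I,1.25,0.0480465,0.0229045
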