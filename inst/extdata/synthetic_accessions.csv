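id,lon,lat
acc1,11.6103,29.3819
acc2,33.8147,21.8998
acc3,-14.0658,8.7975
acc4,36.9142,16.9828
acc5,10.1466,28.8386
acc6,-3.9243,21.1269
acc7,35.6182,17.0007
acc8,1.4397,21.272
acc9,-0.9579,9.1248
acc10,15.5003,20.6235
acc11,-4.5624,14.2507
acc12,-4.3126,28.0379
acc13,18.416,17.0663
acc14,3.2591,11.482
acc15,19.9131,11.1726
acc16,-10.8756,20.3742
acc17,-1.9736,17.3887
acc18,25.8424,16.477
acc19,-4.6921,14.9786
acc20,20.3028,18.0012
acc21,16.2393,10.6258
acc22,-15.1064,14.3968
acc23,-15.7782,19.0577
acc24,23.712,6.5055
acc25,16.3671,9.0457
acc26,7.2334,13.892
acc27,-9.095,9.3614
acc28,34.0221,15.5004
acc29,2.9289,13.9017
acc30,-1.3561,25.3355
acc31,34.9612,14.2435
acc32,17.5184,14.3371
acc33,-4.3902,16.8659
acc34,-12.5962,17.0719
acc35,33.4635,16.2174
acc36,-12.22,26.5107
acc37,12.7284,26.0638
acc38,4.1371,9.8598
acc39,6.9684,29.7552
acc40,2.4319,25.8267
acc41,0.3382,5.4228
acc42,21.3943,13.9238
acc43,-9.7533,6.1089
acc44,23.7195,28.2627
acc45,17.6681,6.8314
acc46,36.4253,16.9091
acc47,-11.142,11.9359
acc48,26.3314,15.5691
acc49,12.8615,18.9826
acc50,20.8399,17.653
acc51,31.4462,14.1969
acc52,33.4099,27.8683
acc53,20.1078,12.5334
acc54,27.9341,28.2391
acc55,39.852,7.509
acc56,0.8416,22.6119
acc57,24.0057,7.7517
acc58,-1.3696,24.9154
acc59,14.5938,11.5338
acc60,-0.4254,27.441
acc61,-0.4983,6.3141
acc62,0.2293,16.0052
acc63,3.9552,28.4512
acc64,3.7366,11.9656
acc65,-8.5063,22.4835
acc66,-2.9751,28.1606
acc67,0.1454,12.542
acc68,0.4913,26.2288
acc69,-11.9316,23.6565
acc70,33.2857,13.7111
acc71,16.5951,9.5673
acc72,29.7933,15.6787
acc73,19.6437,20.9406
acc74,20.6708,10.1376
acc75,32.7773,19.4488
acc76,2.7127,25.6053
acc77,10.3088,10.7069
acc78,-12.2254,19.6988
acc79,-0.2079,7.0551
acc80,2.4023,12.7037
acc81,9.3444,24.5098
acc82,-12.9365,8.3913
acc83,24.119,16.1952
acc84,8.3375,10.411
acc85,-10.87,29.4661
acc86,6.1392,9.3478
acc87,12.6951,21.8283
acc88,-3.9495,24.3073
acc89,16.0903,9.3375
acc90,8.4628,7.5228
acc91,-9.6309,19.6976
acc92,1.5005,17.8237
acc93,29.0385,14.0148
acc94,9.5416,25.5788
acc95,3.1401,26.1207
acc96,11.9587,8.982
acc97,2.1685,26.2784
acc98,24.1885,14.4708
acc99,26.8579,24.1242
acc100,4.2837,23.9011
acc101,22.468,28.7907
acc102,-10.2638,12.7748
acc103,5.6942,18.8468
acc104,29.8617,11.5707
acc105,16.0737,24.531
acc106,36.9506,9.5607
acc107,21.585,25.4809
acc108,14.188,26.6001
acc109,14.5413,27.383
acc110,38.8867,5.9177
acc111,7.7622,6.0429
acc112,28.3447,17.6618
acc113,26.6178,24.4166
acc114,6.046,12.4219
acc115,21.1366,11.5898
acc116,29.5946,14.4576
acc117,2.9003,18.7011
acc118,37.3593,14.0916
acc119,-9.4233,22.9884
acc120,-1.9961,5.0694
acc121,2.6864,5.2358
acc122,5.0343,5.0631
acc123,26.9091,28.5323
acc124,4.5958,21.7795
acc125,29.4083,15.9214
acc126,-12.1288,15.0596
acc127,36.2987,20.8779
acc128,-1.8977,18.8435
acc129,-7.347,17.611
acc130,15.6188,23.0956
acc131,20.4399,13.0367
acc132,18.5951,22.452
acc133,39.8784,15.3259
acc134,23.7921,10.1065
acc135,24.8754,17.3248
acc136,37.0094,9.918
acc137,20.6517,23.6414
acc138,-7.7064,12.4247
acc139,34.0894,10.7392
acc140,8.3435,6.5472
acc141,-1.9236,5.0066
acc142,-2.2135,27.4411
acc143,-13.509,19.351
acc144,28.4478,29.0199
acc145,14.9655,20.1481
acc146,3.8178,26.7123
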