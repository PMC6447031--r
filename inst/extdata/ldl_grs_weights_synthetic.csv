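rsid,effect_allele,beta,maf
rs6159771,C,-1.02472,0.254
rs3595330,A,-0.50821,0.4
rs3370979,C,0.18648,0.153
rs6498017,A,-1.42959,0.34
rs1366208,T,-2.90025,0.411
rs6753437,A,0.074323,0.456
rs4392251,C,-1.26654,0.101
rs7263747,T,-0.0785599,0.398
rs7317024,A,0.373266,0.321
rs7592053,T,-0.125654,0.362
rs6997660,C,3.18701,0.096
rs7132376,G,-0.246025,0.07
rs3466460,T,-3.95644,0.273
rs8591699,T,0.918237,0.387
rs6794427,G,0.0864587,0.212
rs2366832,C,-0.848252,0.343
rs5086387,A,1.26442,0.194
rs8237611,T,-0.0847389,0.39
rs7299267,G,0.995677,0.155
rs5257711,G,0.133504,0.242
rs7131064,T,0.222098,0.255
rs5194508,A,-0.927339,0.187
rs6518642,G,-2.23233,0.151
rs4626164,C,0.626107,0.195
rs5531621,C,0.0442786,0.349
rs5782870,A,0.530355,0.189
rs7690220,C,0.496147,0.313
rs5424900,G,-1.16773,0.265
rs7932680,A,-0.183008,0.461
rs6935270,T,-1.32616,0.311
rs4604594,C,2.10403,0.382
rs5764392,A,-0.38381,0.387
rs8198713,C,-0.298326,0.446
rs4703159,T,0.582528,0.204
rs8713059,A,-0.0293097,0.47
rs5177326,G,0.893127,0.14
rs6057371,A,0.0320738,0.344
rs3915465,A,-0.834547,0.113
rs1421019,G,-1.0253,0.405
rs6363767,C,-0.344764,0.449
rs5387226,C,3.32841,0.353
rs3410778,T,-1.29634,0.091
rs8589253,C,-0.113445,0.281
rs6144937,C,5.65026,0.319
rs7979433,T,-0.122711,0.328
rs1471454,A,-1.89696,0.356
rs8415423,A,0.221719,0.085
rs4455740,G,0.472183,0.235
rs4910261,T,-0.16484,0.407
rs2197013,A,2.91003,0.416
rs1369644,C,-0.113719,0.095
rs6716310,C,0.809879,0.299
rs6143682,T,0.344839,0.144
rs2555302,A,-1.83415,0.263
rs7911214,C,-1.02434,0.496
rs6806534,C,0.0179451,0.097
rs6694925,C,1.99794,0.378
rs3010930,T,0.803385,0.3
rs2653656,C,0.0826608,0.16
rs2776746,G,0.129008,0.453
rs6537610,A,0.557068,0.189
rs7669071,G,-0.174896,0.473
rs2841137,C,1.09139,0.487
rs6543734,G,-0.0751726,0.204
rs5661704,T,-0.111873,0.22
rs7880591,C,1.99428,0.461
rs4323903,C,-2.36433,0.08
rs6404848,G,-0.319177,0.456
rs8072597,G,-0.812864,0.38
rs6805969,A,-2.64404,0.081
rs5299356,A,-1.38846,0.496
rs8794822,C,-1.36087,0.23
rs8860970,A,-0.73444,0.112
rs3949173,A,-0.499409,0.182
rs2741420,C,0.210537,0.071
rs8088873,C,-0.0759006,0.051
rs8545099,C,-0.284318,0.251
rs4259965,A,-0.358038,0.339
rs8539355,G,0.369647,0.18
rs7055665,G,-4.32873,0.109
rs8656173,C,-0.227641,0.196
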