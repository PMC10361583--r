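block	I	II	III	IV	V	VI
1	0.45787349169194169	0.47089179164764328	0.47203787576273443	0.47301817129146362	0.47423172914228023	0.48126109780431847
2	0.35692806999628601	0.38974958925877834	0.3997807713803106	0.40312993107070538	0.40122583023950525	0.41234760761953793
3	0.24276919051556148	0.32056955168703116	0.34075213475165383	0.34391360365134754	0.3417601874559088	0.35330464803119177
4	0.1705001001622046	0.26494601010139585	0.29458068525475073	0.29737603093553083	0.29477322692998448	0.3057613702104775
5	0.1335468021471258	0.22170695846447272	0.25694266551388334	0.25997987746269396	0.25717098313613362	0.26749260221762566
6	0.10856186117458022	0.18771982476075147	0.22714934029418857	0.22971981435559297	0.22716833615881118	0.23648465169192576
7	0.090732165831122827	0.16133307596049143	0.2025310496607349	0.20479691465138242	0.20241421361383677	0.21110985320397038
8	0.077642514210216701	0.14092852656164775	0.18262411096350853	0.18448866553539303	0.18212226379847354	0.19011544341869632
9	0.068286692295204343	0.12644801904881323	0.16541909872370042	0.16737079013310568	0.16508151356415574	0.17255181748468429
10	0.060951046023098546	0.11467910833841363	0.15102931527627683	0.15286899145340521	0.15113317960419304	0.15770176785646997
11	0.054996256011386829	0.10451363132773235	0.13848369161145485	0.14049039793450624	0.13851748047767948	0.14502133176100571
12	0.049915265347764595	0.096004701831982397	0.12802249203129357	0.13004905942146269	0.12822471560432511	0.13409405019818757
13	0.046009291974633861	0.088916361629228849	0.11865616852494162	0.12099010058610987	0.11896073597754193	0.12459854265524149
14	0.042532003688138628	0.082534438077685193	0.11081693541643492	0.11259429859259092	0.11103957171920326	0.11628363033875214
15	0.039361839801870704	0.07705951691260321	0.10429633602073735	0.10549128683081306	0.10406849810938143	0.10895159904783433
16	0.036822158001828031	0.07234669279126256	0.098088137085580673	0.099259863350713559	0.097891143694795527	0.10244474109623936
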