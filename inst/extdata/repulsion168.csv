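alpha,beta
0.56240963472866,0.552133545478
1.04552366269507,0.357551272797
4.42081429181693,1.916320264581
2.77842662680908,0.796884184035
2.67962069337694,1.614563119695
2.94658304443724,1.722023151656
2.62261460917753,1.310196620883
0.86568017061556,2.503119603912
5.00310445704313,1.372823274429
4.12950474928115,1.231199779169
4.99529442257691,1.664544570261
4.74539559643932,1.226634882990
5.32612746598810,0.587504529906
4.96046668224177,1.965933227815
1.87871202490045,1.866365000154
1.54350534607899,0.581270223216
4.79545028068115,0.468627374524
4.52816551968088,2.388487352751
5.76470534372484,1.822637837402
4.74401919670864,1.517437391434
0.75257320083587,0.833652306219
1.73474011257987,2.393874011690
4.27264626066236,0.216218750886
4.87728982330332,0.733501719777
1.32464368620343,2.495976939626
0.50970516612794,1.638574360885
0.30765835657695,1.841295803621
0.03183707313821,0.652976380458
3.54988953099209,1.767005033039
0.72403161096198,1.108083766937
4.48440143209860,1.329662150411
4.38240917005760,1.064685142428
5.23304671798968,1.818658802579
3.83284555473143,1.235596196530
5.24631508179087,2.797596169776
3.10383205335282,0.903206311468
1.04184557718475,2.783390396939
2.82676644396562,2.199306275468
5.64707536916945,0.806683786010
3.13567820398903,1.511617844806
1.56251053739395,1.929862846296
1.64241763023036,1.653982157655
3.82190369051312,2.699644330646
4.21901636414986,0.506996605003
2.19094482443187,1.672655440419
5.86134118515272,0.552279322370
3.46127322486961,0.740992349270
5.26389968076231,1.509372532321
3.89407524179393,0.712244062546
2.40828717779679,1.498444700955
4.05466182524004,1.979154379891
5.50434572307362,1.961237372096
3.25545360253437,1.777755121123
1.08270869424333,0.947839571287
3.41636935319074,2.524613725543
6.12031006241193,1.151516320450
1.76532964892231,1.369936263458
4.95409415597552,2.270902163140
2.14833530732572,2.210524472583
1.24555228998694,1.973717405802
0.13657815195039,1.250385502217
2.96235903054276,0.253819920533
2.16508468889289,0.966054573027
0.92755479235353,1.495378125340
1.81098449209294,0.862776344713
0.03697127896673,2.444086997240
5.80339836221699,2.113918188709
4.67535063241030,0.953705150953
0.40962959540462,1.364177902194
5.22753143838006,2.122104725483
4.08697696094879,2.471552041053
2.92648586434119,2.499198455229
0.34091690456014,2.161650123126
3.85728624010973,1.757173420583
0.45066940578496,2.415678664882
1.31103557982957,1.158353339600
4.48449493584374,2.692657510514
3.05925666150316,1.994923006976
0.91986281772439,1.981285877204
0.02080415949898,2.965856878510
3.40237746483483,1.507223747247
5.85007109842341,2.416334126584
2.17055391121439,1.944133111211
1.20761463058961,1.445389042220
1.42899513922653,0.860157168371
3.69138386290554,1.507595267245
0.07871697315129,2.027009010968
4.92950087403080,2.530461018226
0.33676298003558,2.694265734379
3.71455949100997,2.010874796781
3.97411467215277,1.500196042877
4.22207210316720,2.980718334962
4.30011944622899,2.174483310379
0.10221067538840,0.349509425193
2.02345562398990,0.622885114032
5.79303693949191,1.109241136171
3.39491356235375,2.036973063665
0.77035630297003,1.727729886292
5.00090075652002,1.055974048588
1.48440232309601,1.401729030652
5.92080239433798,1.355654875064
5.50516800528817,2.260143648963
0.72308533277677,2.210615908099
4.72013674415342,1.813691929304
3.59864865317478,0.450444581001
1.91618725485704,0.324986284416
5.49323307042775,1.060488775312
2.32368232607067,1.211786870457
1.92298357852688,1.599173036629
3.12247398558545,2.799842221262
2.88763809018981,1.404175609226
2.39195379801846,0.767399391484
3.38946576737245,1.027738923812
0.21016563557199,1.558872942306
1.36413114472199,1.694146708554
6.00722960031960,1.643332475404
2.05307664289048,2.972268287810
1.08855033510470,2.242517092708
3.52611119872629,1.262326124778
0.07631054683909,0.961834824344
2.47309379630994,2.088280327757
0.00465653109133,1.744539301943
5.48516796701123,1.667840952517
4.25458089940966,1.479959637066
1.94036173261816,1.148230647048
2.45702501674442,1.801220963064
2.54460962129011,0.495875467680
0.76075166466428,0.074796450768
4.66124157096489,2.111076047506
4.07107708831748,0.953516381315
1.07905644493754,0.651131354350
6.21430507350103,1.447586130714
3.17887609279408,1.235523992926
3.07521223507988,0.579687076088
0.38175680163496,0.814424278949
2.10673555522363,1.384543704173
5.24192053914969,0.867367409034
5.38834538074799,2.511164772063
2.56443854792418,1.029571504833
0.99989897182132,1.221710556277
2.13527180592502,2.480716199436
1.75315503373150,2.698907546208
0.58305394510499,1.952097225801
6.01159989606529,0.865465554775
3.72015663140696,0.978811273930
0.41360573638305,1.088771183499
1.44954431396844,2.201355392839
5.46718905581243,0.295322153005
1.81600572326039,2.127283123306
3.93929662872567,2.236335235728
5.54157052555351,1.342423569289
6.05347515547421,1.929334016739
2.88468540376219,1.116746568231
2.73660330268603,1.920326529783
0.68291168474376,1.386912080491
1.61643128080588,1.110162733198
3.59637326022001,2.291754439622
5.93688003639189,2.685016566540
2.47802044507810,2.686555182294
5.25411164934068,1.223246314950
4.39397403185618,0.757915276218
4.48832050818476,1.638833164365
5.72728590267777,1.539266260210
6.13839136998881,2.215942092802
1.07979005424356,1.733544748042
2.52874760977186,2.368429730765
4.18032765109693,1.742984217804
3.19258579169742,2.267981073920
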