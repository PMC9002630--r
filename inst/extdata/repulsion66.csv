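alpha,beta
1.9560670045878,1.042482728064
5.1601715966344,0.737902638479
4.3020433433413,2.255625013752
1.5535170429695,1.278926205672
0.4923972828881,1.120695255966
0.7316129850880,1.503332260421
1.1854076743260,1.524799230363
2.8493879313334,1.974120661711
1.0106466647672,1.939032714979
4.4012483515972,1.275271624601
0.5276267382160,1.915534215379
2.2758397002710,1.381747420482
3.0035696046136,0.691774234532
0.0705516851959,2.502323862559
3.3557848204794,1.978657446183
0.7769144458216,0.704616608742
3.0358319937641,0.231422929198
4.1013343741964,2.733167620989
5.1605396648881,1.619312504006
3.5697048013125,1.507314814930
1.4726032262157,0.786969681599
0.7046552539403,2.341091847022
1.1755846457605,0.313678900287
2.1609518569078,0.582584186725
5.6205025216643,2.471852347669
0.2512262128103,1.552661060090
1.3530409634744,2.290291742074
5.7697809837446,0.830820553582
5.8598143503173,2.068210777873
4.8849543236708,1.145803283019
1.8926436555519,1.594263129803
2.9598886088528,1.164855394780
5.3093654426811,2.069136676686
3.9388058597445,1.057601416073
5.6358480975880,2.928785681271
1.0421041891919,1.102911040702
0.9966292361539,2.766313625935
2.4566724803178,2.297333618552
6.2677270010526,1.175943501320
6.0942854399983,1.654312761422
4.8075820719921,2.028276488034
4.3388438833387,1.808875167520
2.7352646138305,2.854375953663
0.1121827912189,0.735278917198
4.0059935500909,1.498843465371
4.6263615476309,0.375179442877
4.4594010394594,0.817550912678
2.6881491648484,1.536759369753
3.7543273981996,0.630223811069
3.1443104453324,1.577614582478
0.0803040388126,2.051966249764
1.9137950080451,2.084247041838
3.8505362575109,1.923158689581
5.3596393712285,1.202396508920
1.9049818876922,2.554342985030
2.5035585594391,0.980949687791
3.4327530844027,1.068487958535
3.0635069173213,2.426109233785
4.8959448549146,2.483684362418
2.3354192712058,1.848026726706
5.6028210275599,1.678556256944
5.9373303513499,0.348830346201
1.5100830798772,1.831576827651
4.7309069440733,1.581857217294
5.8165972725401,1.282650405930
3.6938302780799,2.353817756464
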