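"f1","f2"
-0.131122595424374,0.828833481839139
-0.145799895543701,3.88657054831713
-0.362064721117229,1.35265659767423
-0.673981163800475,1.38939582919986
-2.07203576815057,0.311758979827161
0.541028649061476,2.03710503250927
1.0704921583121,1.99405236529072
0.372456732278273,1.68114584024097
0.485141354788276,2.20293719188641
-0.274784178475709,2.73741587896086
0.479512561582301,1.53168149461106
-0.798105326125375,1.01551877914489
1.00445120238872,1.52983456869907
-0.104984233069838,2.3213528353238
1.15599289019211,2.15698483893634
-0.578134626957855,1.60593682227986
1.59562565619352,3.49828023303417
0.308503656205915,2.64991334760769
-0.449465922122598,2.81636924901767
0.977053282629373,2.01609592767709
-0.189997859367245,2.53304249213478
-0.731453357300176,4.31660253370394
0.492599110754294,3.32138019482565
0.0426849121739954,2.00694183159024
0.112670576433895,1.28415623774484
-0.456827247726431,2.04201624676422
-2.02033484176677,2.11029541564374
-0.72594044914642,-2.20559060083231
-1.79788966167536,-0.420048432484063
-3.16446587974116,-0.615450794427704
-1.97662059147613,-2.46897333532962
-2.89715674990079,-1.40473926043712
-1.82327554506841,-0.840495941942423
-3.11370907755827,-0.748153844700979
-1.45811114035005,-0.160279938588728
-1.03660166811873,-0.298932106621485
-2.37644839958196,-0.957571621526731
-1.01532620328652,-0.320375500834238
-2.8975594022735,-0.307910385971513
-2.12926253348537,0.799404716228458
-3.0337029805641,-3.30396053994629
-1.65771072637231,-0.18358026866923
-2.45228125653568,-0.00963896508671791
-1.30526205797304,-1.68010116447798
-1.76098640894712,-0.90438043560508
-0.992701040409739,-1.58410714974895
-3.92671883293018,-1.33722016052622
-2.05143036448265,-1.25801100476393
-3.80052376157027,-1.78853874159109
-1.448542238598,-2.42575432558253
-2.10705889450465,-1.53865093228249
-2.78912404424383,-0.637944736016067
-1.75574468248446,-1.33266908219046
-2.38417996419341,-1.15044249971597
2.2782374383072,-2.32393605239497
0.943158676478385,0.363571887910915
1.63248556279624,-1.08171936123145
1.1524853852456,-1.68237556707542
3.26282046598614,-1.6792261178198
1.47176333220335,-0.407799790186193
0.910593177746472,-2.33711450994811
2.69947836396075,-2.5094090221646
0.578973831601418,-1.36698604741672
0.560978321501764,-1.24418203305721
3.29531128491286,-0.897668025446893
2.89705986679236,0.0495862982974444
3.88477611635603,-1.32873161519865
1.97250209507917,-0.46448374732596
2.90741665262598,-0.741315956613276
3.64756170283582,-2.58517958571798
1.74765996090489,-2.45436964027719
1.35768573484974,0.248649329342977
2.34693610770745,-1.37405075713363
2.51526323154854,0.977790553441195
1.60183107666989,-2.98817044804
1.04644278634788,-1.26521021902712
1.7398210756159,-0.388990185610949
4.05013437683161,-0.831195933952248
1.71202928242427,-1.89007945023173
1.63805458082192,-0.0089833947072131
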