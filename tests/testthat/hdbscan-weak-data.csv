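"f1","f2"
-1.60034034508296,0.554326939220179
-3.09003352696834,-0.280271939952888
-2.06649487611176,1.77516336956021
-3.11447949380622,0.187320121673427
-1.031349840775,1.14252614647565
-0.773898599451958,0.415526133492785
-0.476660998136555,1.22950655592903
0.437815526578841,0.236679672240931
-1.77714728924503,-0.365382773252059
-2.90835366660647,1.10514427225028
-1.77312918928982,-1.09359397160108
-2.25552506891792,0.461870908226753
-1.15098158863852,-1.36098453256021
-0.953809240985648,-1.85602715431898
-1.7343619949503,-0.439855409163339
-1.20217177781958,-0.193946900574085
-0.659523867218599,1.39643151363809
-2.32651035605547,0.100663245719
-2.98369123109091,-0.114438810048087
-2.1996756414182,0.702225229925947
-0.238425848863798,0.262542670981165
-1.79827174370042,1.83616330184588
-1.35219289405331,0.35740241881979
-0.611077666340808,-1.04541012650827
-2.51306585838081,0.620184127337731
-0.579474917403445,0.149354529304505
-0.926105495806136,-1.45931685394734
-2.65036548458217,-2.02704380077946
-2.64382456210206,-1.05695776024492
-1.26055723723173,-0.728143715858865
-0.413197850650643,-0.00821067005591938
-1.43855301483271,0.847797375737756
-0.983302655626454,-0.383491495680503
0.407673688956481,-0.526511510275127
-1.60715648130844,-0.273225962809109
-0.322624812404839,-0.605741605348354
-3.24542691251586,-0.33286730546774
-1.10130147341696,-0.241537545517952
-1.94243942439518,-0.862775399222633
-1.95027946208908,-0.846970752447282
0.174519133212877,-0.0760621578891206
1.04581239217955,0.297513215720422
1.58334854835603,-1.19435471065916
1.57140836856509,-1.99687548467608
2.8454962950468,1.38851304735604
1.7008767067727,-0.082483573565011
1.73633846444457,0.392514487605017
1.55784449859907,-1.08276971342343
2.53193984001577,1.60212039143709
2.3665491592666,1.00406896944236
0.6523890436125,0.379895700157524
1.37657810809631,-0.56550536431604
1.09847809963926,-1.21377809780239
0.577674298539848,-1.36430159260496
-0.286593463217436,-1.41613295003786
1.67929586607345,-0.255578030421819
1.89248338881802,-1.22542595393505
0.777937254137067,0.213834264499421
0.541475742362079,0.067223555567545
2.79546707919027,0.856635112998544
1.16063828354628,-0.369172685817411
2.64776268403772,0.611497436400254
2.59091788503763,-1.62875731810285
3.49362881117498,0.142357677645981
1.06974184424461,-0.26469300438163
-0.207179200975147,-0.501570813345008
3.08225162487002,1.22340537525747
1.85700352158453,0.432052180091422
3.19865355161657,-0.00681044795777621
2.65197034100531,1.67302400860416
4.34476384485171,-0.866516711061801
-0.214577589973355,1.63614588957735
2.72881682091195,-1.0211025594487
1.81407296063893,-0.811764471796863
1.56991232429027,-0.0507628582433116
2.33760143111919,-0.112591404684118
1.25313944442075,0.852650289544179
4.07512822614232,0.747346696857889
1.49569806568069,0.389468268028977
-0.845962581668275,-0.18601957575098
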