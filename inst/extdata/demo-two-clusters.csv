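"f1","f2",".cluster"
-4.67132798590976,0.520589072918523,1
-4.83531842307416,-1.07969076235228,1
-3.6079711202287,0.139238115019273,1
-6.46582476120139,-0.0847487849485765,1
-5.04820680822544,-0.666639615284596,1
-6.90808383464199,-2.51608903200946,1
-6.73094452723732,-0.735146797456677,1
-5.0581458372593,-1.02012226313509,1
-5.64532816177517,0.113554441297307,1
-6.7256289865063,-0.473790981840095,1
-4.47103308254375,-0.408214704337928,1
-5.16639202561255,-0.730433278593614,1
-4.74527642523605,-0.221436599406174,1
-5.33278235943791,-0.225816524428951,1
-5.18243281282763,-2.5468814461283,1
-6.164593749518,1.34700149929703,1
-5.59349285072787,0.616408145849969,1
-4.10822027078263,0.217564338307888,1
-5.5772533103574,-0.804718830400263,1
-4.17509441894196,0.68974677762582,1
5.14147069081321,-1.15725385762344,2
4.83267010035119,0.777998774006214,2
5.19878861267168,-1.20422178597307,2
5.2912071880921,0.30671410214768,2
6.73439703424929,-0.833658540642056,2
5.2727283317326,1.41814116350375,2
6.79992948169682,0.711786117850718,2
3.84725902319696,-0.402497722862373,2
6.003319485592,0.799362218714509,2
4.85178995570746,0.426484435556948,2
4.48050331925082,-1.16989866993562,2
4.99456370552424,-0.206200160293019,2
3.65297916534606,-0.930610309243612,2
5.847033417296,0.449397565791737,2
4.55660198268423,-0.644806454562313,2
5.97714946832331,-0.231422689810958,2
2.87550886448639,-1.23636801144537,2
4.31230103943846,-0.960955298223015,2
5.3433682201804,0.133956281569561,2
4.21483052732605,-0.999052722969284,2
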