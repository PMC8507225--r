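age,sex,qx
0,F,0.000415895621429518
1,F,0.000417496504490633
2,F,0.000419257807195428
3,F,0.000421195604383917
4,F,0.000423327581605792
5,F,0.000425673196500109
6,F,0.000428253856340821
7,F,0.000431093113366532
8,F,0.000434216879676708
9,F,0.000437653663650561
10,F,0.000441434830045995
11,F,0.000445594886146372
12,F,0.000450171796565257
13,F,0.000455207329572715
14,F,0.00046074743810276
15,F,0.000466842678905954
16,F,0.000473548673667334
17,F,0.000480926616284183
18,F,0.000489043830920521
19,F,0.000497974385913147
20,F,0.000507799769113082
21,F,0.000518609630800193
22,F,0.000530502600920468
23,F,0.000543587188068573
24,F,0.000557982768376042
25,F,0.000573820673275494
26,F,0.000591245386003636
27,F,0.000610415857684066
28,F,0.000631506954905214
29,F,0.000654711051888301
30,F,0.000680239781637226
31,F,0.000708325961879863
32,F,0.000739225713174196
33,F,0.000773220788259255
34,F,0.000810621133607969
35,F,0.000851767706194217
36,F,0.000897035570738502
37,F,0.000946837305162873
38,F,0.00100162674468685
39,F,0.00106190309794729
40,F,0.00112821547175956
41,F,0.00120116784466184
42,F,0.00128142453324287
43,F,0.00136971619945303
44,F,0.00146684645168771
45,F,0.00157369909741534
46,F,0.00169124611055871
47,F,0.00182055638272549
48,F,0.00196280533378768
49,F,0.00211928546423068
50,F,0.00229141793918175
51,F,0.00248076530210184
52,F,0.00268904542481752
53,F,0.002918146809892
54,F,0.00317014537131632
55,F,0.00344732283013138
56,F,0.00375218687288192
57,F,0.00408749323272395
58,F,0.0044562698655205
59,F,0.00486184340630968
60,F,0.00530786810501016
61,F,0.00579835745401935
62,F,0.00633771873426392
63,F,0.00693079072005542
64,F,0.00758288479645208
65,F,0.00829982975533261
66,F,0.00908802054753322
67,F,0.00995447127751725
68,F,0.0109068727333375
69,F,0.0119536547470794
70,F,0.0131040536783081
71,F,0.0143681853037222
72,F,0.0157571233784006
73,F,0.0172829841054163
74,F,0.0189590167084661
75,F,0.0207997002432291
76,F,0.0228208467034996
77,F,0.0250397103730835
78,F,0.0274751032384968
79,F,0.0301475161042208
80,F,0.0330792448341242
81,F,0.0362945208709888
82,F,0.0398196448509283
83,F,0.0436831217195935
84,F,0.0479157952598304
85,F,0.0525509793419835
86,F,0.0576245824933471
87,F,0.0631752215365261
88,F,0.0692443190516533
89,F,0.0758761782589911
90,F,0.0831180275827379
91,F,0.0910200256336273
92,F,0.099635215632817
93,F,0.109019416397318
94,F,0.119231034935745
95,F,0.130330783499032
96,F,0.142381281655806
97,F,0.155446521711978
98,F,0.169591173707736
99,F,0.184879704496699
100,F,0.201375284302971
101,F,0.219138454004521
102,F,0.238225527640867
103,F,0.258686707826824
104,F,0.280563897515283
105,F,0.303888200632209
106,F,0.328677117322867
107,F,0.354931457743247
108,F,0.382632022293568
109,F,0.411736126530036
110,F,1
0,M,0.000623778564209476
1,M,0.000626179388437897
2,M,0.000628820789770557
3,M,0.000631726874753546
4,M,0.000634924165326067
5,M,0.000638441840802417
6,M,0.000642312004089374
7,M,0.000646569974564692
8,M,0.000651254610285368
9,M,0.000656408662462193
10,M,0.000662079165425822
11,M,0.000668317865638035
12,M,0.000675181693652549
13,M,0.000682733283320469
14,M,0.000691041542964288
15,M,0.000700182283716155
16,M,0.000710238910732852
17,M,0.000721303183569111
18,M,0.000733476052618642
19,M,0.000746868579216908
20,M,0.000761602947757178
21,M,0.000777813578999975
22,M,0.000795648354668943
23,M,0.000815269964425269
24,M,0.000836857387415346
25,M,0.000860607521789958
26,M,0.000886736976919988
27,M,0.000915484044487824
28,M,0.000947110866225898
29,M,0.000981905817827644
30,M,0.00102018613046784
31,M,0.00106230077347669
32,M,0.00110863362401159
33,M,0.00115960695209238
34,M,0.00121568525212701
35,M,0.00127737945507178
36,M,0.00134525155867316
37,M,0.00141991971684208
38,M,0.00150206383315032
39,M,0.00159243170772994
40,M,0.00169184579154025
41,M,0.00180121060705674
42,M,0.0019215208999781
43,M,0.00205387059256223
44,M,0.0021994626157229
45,M,0.00235961970407883
46,M,0.00253579624577538
47,M,0.00272959128712091
48,M,0.00294276280092187
49,M,0.00317724333688707
50,M,0.00343515718260423
51,M,0.00371883917438764
52,M,0.00403085530873815
53,M,0.00437402531722719
54,M,0.00475144738026312
55,M,0.00516652516836402
56,M,0.00562299741312722
57,M,0.00612497022391945
58,M,0.00667695238021671
59,M,0.00728389384322647
60,M,0.00795122774361545
61,M,0.00868491611437971
62,M,0.00949149964860985
63,M,0.0103781517704066
64,M,0.0113527373126443
65,M,0.0124238760965875
66,M,0.0136010117042106
67,M,0.0148944857228652
68,M,0.0163156177216911
69,M,0.0178767911875192
70,M,0.0195915456020963
71,M,0.0214746747788322
72,M,0.0235423314918447
73,M,0.0258121383179964
74,M,0.0283033044681628
75,M,0.0310367482004326
76,M,0.0340352241775536
77,M,0.0373234548446854
78,M,0.0409282645511789
79,M,0.0448787147100539
80,M,0.0492062377681741
81,M,0.0539447671346515
82,M,0.0591308594694999
83,M,0.0648038048531029
84,M,0.0710057193236372
85,M,0.0777816130690291
86,M,0.0851794261792757
87,M,0.0932500222950182
88,M,0.102047128726668
89,M,0.111627209672669
90,M,0.122049257057592
91,M,0.133374481282802
92,M,0.145665881903685
93,M,0.158987676023147
94,M,0.173404560172775
95,M,0.188980779849939
96,M,0.20577897997155
97,M,0.223858809656876
98,M,0.243275256422451
99,M,0.26407668862483
100,M,0.286302591490156
101,M,0.309980992086192
102,M,0.335125582951044
103,M,0.361732573632467
104,M,0.389777324870171
105,M,0.419210852109684
106,M,0.449956323594476
107,M,0.481905722895795
108,M,0.51491689486797
109,M,0.54881124476413
110,M,1
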