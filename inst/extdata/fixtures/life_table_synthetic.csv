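"age","qx"
0,0.000301154643833845
1,0.000301321187709425
2,0.000301510852568132
3,0.000301726848248807
4,0.000301972830203723
5,0.000302252961362104
6,0.000302571982580657
7,0.000302935292875395
8,0.000303349040789991
9,0.000303820228450324
10,0.000304356830061137
11,0.000304967926855415
12,0.000305663860774685
13,0.00030645640948479
14,0.000307358985685902
15,0.000308386864089405
16,0.000309557439902686
17,0.00031089052319444
18,0.000312408674119413
19,0.000314137584675245
20,0.000316106513446823
21,0.000318348780693811
22,0.000320902332152539
23,0.000323810381088196
24,0.000327122139453517
25,0.000330893650517083
26,0.000335188737035086
27,0.000340080080996064
28,0.000345650453183577
29,0.000351994113333975
30,0.000359218404540451
31,0.000367445568831948
32,0.000376814814578075
33,0.000387484670616112
34,0.000399635666815445
35,0.0004134733862875
36,0.000429231940687114
37,0.000447177927154319
38,0.000467614933513549
39,0.000490888667525446
40,0.000517392796411498
41,0.000547575594720962
42,0.000581947512061531
43,0.000621089787494755
44,0.000665664254728582
45,0.000716424501903457
46,0.000774228572057001
47,0.000840053415600339
48,0.000915011334721605
49,0.00100036869195685
50,0.00109756719169052
51,0.00120824808456088
52,0.00133427969119959
53,0.00147778869399517
54,0.00164119570427679
55,0.00182725567810815
56,0.00203910382743855
57,0.00228030775535193
58,0.0025549266352427
59,0.00286757835450668
60,0.0032235156542586
61,0.00362871241795326
62,0.00408996139361317
63,0.004614984776246
64,0.00521255922798491
65,0.00589265707169773
66,0.00666660555637388
67,0.00754726625508895
68,0.00854923681233399
69,0.00968907739789004
70,0.0109855643366698
71,0.0124599734509165
72,0.0141363956499267
73,0.0160420872025991
74,0.0182078568897267
75,0.02066849180416
76,0.023463222881106
77,0.0266362302128692
78,0.0302371867251338
79,0.0343218367317731
80,0.0389526030776058
81,0.0441992128239143
82,0.0501393264921406
83,0.0568591494801667
84,0.0644539960902932
85,0.0730287663199333
86,0.0826982828216113
87,0.0935874199269074
88,0.10583093813181
89,0.119572915929419
90,0.134965646650312
91,0.152167841861039
92,0.171341956510303
93,0.192650427193048
94,0.216250598016369
95,0.242288105086595
96,0.270888509676997
97,0.302147023724916
98,0.336116274465894
99,0.37279222503973
100,0.412098622452727
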