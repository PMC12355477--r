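"age","sex","qx"
15,"male",0.000515723
16,"male",0.000526621
17,"male",0.000538545
18,"male",0.000551593
19,"male",0.000565869
20,"male",0.000581489
21,"male",0.000598581
22,"male",0.000617282
23,"male",0.000637745
24,"male",0.000660134
25,"male",0.000684632
26,"male",0.000711437
27,"male",0.000740766
28,"male",0.000772858
29,"male",0.000807972
30,"male",0.000846392
31,"male",0.000888431
32,"male",0.000934428
33,"male",0.000984758
34,"male",0.00103983
35,"male",0.00110008
36,"male",0.00116601
37,"male",0.00123815
38,"male",0.00131708
39,"male",0.00140345
40,"male",0.00149795
41,"male",0.00160135
42,"male",0.00171448
43,"male",0.00183827
44,"male",0.00197372
45,"male",0.00212192
46,"male",0.00228408
47,"male",0.00246152
48,"male",0.00265566
49,"male",0.00286808
50,"male",0.00310051
51,"male",0.00335483
52,"male",0.0036331
53,"male",0.00393758
54,"male",0.00427073
55,"male",0.00463525
56,"male",0.0050341
57,"male",0.00547051
58,"male",0.00594803
59,"male",0.00647051
60,"male",0.00704219
61,"male",0.00766772
62,"male",0.00835215
63,"male",0.00910104
64,"male",0.00992045
65,"male",0.010817
66,"male",0.011798
67,"male",0.0128715
68,"male",0.0140459
69,"male",0.015331
70,"male",0.0167372
71,"male",0.0182757
72,"male",0.0199591
73,"male",0.0218011
74,"male",0.0238165
75,"male",0.0260218
76,"male",0.0284347
77,"male",0.0310748
78,"male",0.0339636
79,"male",0.0371244
80,"male",0.0405829
81,"male",0.0443671
82,"male",0.0485077
83,"male",0.0530382
84,"male",0.0579954
85,"male",0.0634194
86,"male",0.0693542
87,"male",0.0758479
88,"male",0.0829531
89,"male",0.0907275
90,"male",0.099234
91,"male",0.108542
92,"male",0.118726
93,"male",0.129869
94,"male",0.142062
95,"male",0.155403
96,"male",0.17
97,"male",0.185972
98,"male",0.203448
99,"male",0.22257
100,"male",1
15,"female",0.000279498
16,"female",0.000287159
17,"female",0.000295558
18,"female",0.000304766
19,"female",0.000314862
20,"female",0.000325931
21,"female",0.000338066
22,"female",0.000351371
23,"female",0.000365958
24,"female",0.00038195
25,"female",0.000399484
26,"female",0.000418707
27,"female",0.000439783
28,"female",0.000462889
29,"female",0.000488222
30,"female",0.000515997
31,"female",0.000546448
32,"female",0.000579833
33,"female",0.000616436
34,"female",0.000656566
35,"female",0.000700562
36,"female",0.000748799
37,"female",0.000801684
38,"female",0.000859665
39,"female",0.000923234
40,"female",0.000992928
41,"female",0.00106934
42,"female",0.00115311
43,"female",0.00124496
44,"female",0.00134566
45,"female",0.00145606
46,"female",0.0015771
47,"female",0.0017098
48,"female",0.00185529
49,"female",0.0020148
50,"female",0.00218969
51,"female",0.00238142
52,"female",0.00259163
53,"female",0.0028221
54,"female",0.00307478
55,"female",0.00335181
56,"female",0.00365553
57,"female",0.00398853
58,"female",0.00435361
59,"female",0.00475387
60,"female",0.0051927
61,"female",0.00567382
62,"female",0.00620131
63,"female",0.00677962
64,"female",0.00741366
65,"female",0.00810881
66,"female",0.00887094
67,"female",0.00970651
68,"female",0.0106226
69,"female",0.011627
70,"female",0.0127281
71,"female",0.0139354
72,"female",0.015259
73,"female",0.0167102
74,"female",0.0183012
75,"female",0.0200455
76,"female",0.0219579
77,"female",0.0240546
78,"female",0.0263533
79,"female",0.0288736
80,"female",0.0316367
81,"female",0.0346661
82,"female",0.0379874
83,"female",0.0416288
84,"female",0.0456211
85,"female",0.0499981
86,"female",0.0547969
87,"female",0.0600581
88,"female",0.0658263
89,"female",0.0721504
90,"female",0.0790839
91,"female",0.0866855
92,"female",0.0950197
93,"female",0.104157
94,"female",0.114175
95,"female",0.125158
96,"female",0.137199
97,"female",0.150401
98,"female",0.164876
99,"female",0.180744
100,"female",1
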