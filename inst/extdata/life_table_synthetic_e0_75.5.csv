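"age","ex"
0,75.4999999998939
1,74.5024894266351
2,73.5052014214193
3,72.5081553556348
4,71.5113722238251
5,70.514874772087
6,69.5186876356852
7,68.5228374864252
8,67.5273531903421
9,66.5322659762756
10,65.537609615914
11,64.5434206158957
12,63.5497384225608
13,62.5566056399477
14,61.5640682616173
15,60.5721759168813
16,59.5809821319861
17,58.5905446067778
18,57.6009255073351
19,56.6121917750067
20,55.6244154522293
21,54.6376740254244
22,53.6520507851823
23,52.6676352038312
24,51.6845233303599
25,50.7028182025143
26,49.7226302757112
27,48.7440778682169
28,47.767287621808
29,46.792394976877
30,45.8195446606562
31,44.84889118691
32,43.8805993650904
33,42.9148448165538
34,41.9518144950058
35,40.991707207869
36,40.0347341347618
37,39.0811193387236
38,38.1311002652455
39,37.1849282235404
40,36.2428688438458
41,35.3052025038761
42,34.3722247168551
43,33.4442464728568
44,32.5215945244898
45,31.6046116072732
46,30.6936565844008
47,29.7891045049848
48,28.8913465643277
49,28.0007899543262
50,27.1178575917754
51,26.2429877121531
52,25.3766333164471
53,24.5192614587779
54,23.6713523629966
55,22.8333983571348
56,22.0059026155884
57,21.1893777002529
58,20.3843438935288
59,19.5913273182066
60,18.8108578417278
61,18.0434667652269
62,17.2896843010697
63,16.5500368463172
64,15.8250440636204
65,15.1152157854545
66,14.4210487622575
67,13.7430232798799
68,13.0815996766599
69,12.4372147953087
70,11.8102784094682
71,11.201169669147
72,10.6102336130714
73,10.0377777991386
74,9.48406910645118
75,8.94933076367506
76,8.43373965853807
77,7.93742398204847
78,7.46046125835175
79,7.00287680700788
80,6.56464267884781
81,6.14567709950387
82,5.74584444631307
83,5.36495577473448
84,5.00276989993462
85,4.6589950280651
86,4.33329092032042
87,4.02527156149009
88,3.73450829379715
89,3.46053336673267
90,3.20284384472528
91,2.96090580715553
92,2.73415876971339
93,2.52202025260261
94,2.3238904197357
95,2.13915671385982
96,1.96719841543769
97,1.80739105791621
98,1.6591106385103
99,1.52173757150303
100,1.39466033996132
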