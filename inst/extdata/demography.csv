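age,p_death_month,p_hyst_month
0,4.22241085372699e-05,0
1,4.2279749047025e-05,0
2,4.23409346226311e-05,0
3,4.24082178784868e-05,0
4,4.24822065012709e-05,0
5,4.25635687392178e-05,0
6,4.26530394369573e-05,0
7,4.27514266727602e-05,0
8,4.2859619056701e-05,0
9,4.29785937562377e-05,0
10,4.31094253218189e-05,0
11,4.32532953915654e-05,0
12,4.34115033639548e-05,0
13,4.35854781328793e-05,0
14,4.37767909930997e-05,0
15,4.39871698315608e-05,0
16,4.42185147332408e-05,0
17,4.44729151412027e-05,0
18,4.47526687278321e-05,1.2310614256883e-05
19,4.50603021461271e-05,1.70750775903006e-05
20,4.53985938495549e-05,2.33928777271242e-05
21,4.57705991847579e-05,3.16550157022366e-05
22,4.61796779859247e-05,4.23096308309612e-05
23,4.66295249188509e-05,5.58564911474768e-05
24,4.71242028484697e-05,7.28359281508828e-05
25,4.76681795318346e-05,9.38112967653337e-05
26,4.82663679668427e-05,0.000119344379181707
27,4.89241707634092e-05,0.000149963661306929
28,4.96475289341047e-05,0.00018612608227575
29,5.04429755476821e-05,0.00022817365460448
30,5.13176947296579e-05,0.000276287211192328
31,5.22795865405268e-05,0.000330440365952533
32,5.33373383198033e-05,0.000390357468916136
33,5.45005031387102e-05,0.000455479778343371
34,5.57795860698374e-05,0.000524944153977747
35,5.71861390525896e-05,0.00059757821509443
36,5.87328652111863e-05,0.00067191506534714
37,6.04337335659011e-05,0.000746229380989116
38,6.23041051736051e-05,0.000818594970775299
39,6.43608718354782e-05,0.000886961987365598
40,6.66226086242228e-05,0.000949249994034118
41,6.91097416058994e-05,0.00100345128871304
42,7.18447322715088e-05,0.00104773748298759
43,7.48522803393215e-05,0.00108056152019942
44,7.81595467612695e-05,0.0011007472293717
45,8.1796398940015e-05,0.00110755920416694
46,8.57956803723692e-05,0.0011007472293717
47,9.01935071474513e-05,0.00108056152019942
48,9.50295939738943e-05,0.00104773748298759
49,0.00010034761267419,0.00100345128871304
50,0.000106195586377145,0.000949249994034118
51,0.000112626322959275,0.000886961987365598
52,0.000119697891640014,0.000818594970775299
53,0.000127474147021966,0.000746229380989116
54,0.000136025305294218,0.00067191506534714
55,0.000145428577782658,0.00059757821509443
56,0.000155768867549311,0.000524944153977747
57,0.000167139535301897,0.000455479778343371
58,0.00017964324149955,0.000390357468916136
59,0.00019339287222131,0.000330440365952533
60,0.000208512557107743,0.000276287211192328
61,0.000225138788515045,0.00022817365460448
62,0.000243421651915376,0.00018612608227575
63,0.000263526178572615,0.000149963661306929
64,0.000285633832604937,0.000119344379181707
65,0.000309944145741703,9.38112967653337e-05
66,0.000336676514386625,7.28359281508828e-05
67,0.000366072175034926,5.58564911474768e-05
68,0.000398396375664523,4.23096308309612e-05
69,0.000433940762445295,3.16550157022366e-05
70,0.000473026002997812,2.33928777271242e-05
71,0.000516004669503745,1.70750775903006e-05
72,0.000563264407234088,1.2310614256883e-05
73,0.000615231416539297,8.76667356253247e-06
74,0.000672374279060084,6.16634873396027e-06
75,0.000735208161877665,4.28409914621231e-06
76,0.000804299436565792,2.93987704169663e-06
77,0.000880270753638945,1.99267776079814e-06
78,0.000963806616752105,1.33408425351256e-06
79,0.00105565950521058,8.82201388940906e-07
80,0.00115665659792974,5.76222913939439e-07
81,0.00126770715696589,3.71750558003647e-07
82,0.00138981063415189,2.36892362170948e-07
83,0.00152406557024631,1.49103836277753e-07
84,0.00167167936236934,9.26968356518287e-08
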