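"number","name","side","role","gpa_excluded"
1,"Glabella","midline","LM",FALSE
2,"Ophryon","midline","LM",FALSE
3,"Metopion","midline","LM",FALSE
4,"Nasion","midline","LM",FALSE
5,"Rhinion","midline","LM",FALSE
6,"Nasospinale","midline","LM",FALSE
7,"Subspinale","midline","LM",FALSE
8,"Prosthion","midline","LM",FALSE
9,"Orale","midline","LM",FALSE
10,"Staphylion","midline","LM",FALSE
11,"Hormion","midline","LM",FALSE
12,"Sphenobasion","midline","LM",FALSE
13,"Basion","midline","LM",FALSE
14,"Opisthion","midline","LM",FALSE
15,"Inion","midline","LM",FALSE
16,"Obelion","midline","LM",FALSE
17,"Vertex","midline","LM",FALSE
18,"Euryon_L","L","LM",TRUE
19,"Euryon_R","R","LM",TRUE
20,"Frontotemporale_L","L","LM",FALSE
21,"Frontotemporale_R","R","LM",FALSE
22,"Stephanion_L","L","LM",FALSE
23,"Stephanion_R","R","LM",FALSE
24,"Coronale_L","L","LM",FALSE
25,"Coronale_R","R","LM",FALSE
26,"Pterion_L","L","LM",FALSE
27,"Pterion_R","R","LM",FALSE
28,"Maxillofrontale_L","L","LM",FALSE
29,"Maxillofrontale_R","R","LM",FALSE
30,"Ectoconchion_L","L","LM",FALSE
31,"Ectoconchion_R","R","LM",FALSE
32,"Supraorbitale_L","L","LM",FALSE
33,"Supraorbitale_R","R","LM",FALSE
34,"Orbitale_L","L","LM",FALSE
35,"Orbitale_R","R","LM",FALSE
36,"Dacryon_L","L","LM",FALSE
37,"Dacryon_R","R","LM",FALSE
38,"Zygoorbitale_L","L","LM",FALSE
39,"Zygoorbitale_R","R","LM",FALSE
40,"Frontomalare_orbitale_L","L","LM",FALSE
41,"Frontomalare_orbitale_R","R","LM",FALSE
42,"Frontomalare_temporale_L","L","LM",FALSE
43,"Frontomalare_temporale_R","R","LM",FALSE
44,"Alare_L","L","LM",FALSE
45,"Alare_R","R","LM",FALSE
46,"Nariale_L","L","LM",FALSE
47,"Nariale_R","R","LM",FALSE
48,"Bregma","midline","LM",FALSE
49,"Lambda","midline","LM",FALSE
50,"Opisthocranion","midline","LM",FALSE
51,"Auriculare_L","L","LM",FALSE
52,"Sphenion_L","L","LM",FALSE
53,"Sphenion_R","R","LM",FALSE
54,"Krotaphion_L","L","LM",FALSE
55,"Krotaphion_R","R","LM",FALSE
56,"Auriculare_R","R","LM",FALSE
57,"Porion_L","L","LM",FALSE
58,"Entomion_L","L","LM",FALSE
59,"Entomion_R","R","LM",FALSE
60,"Asterion_L","L","LM",FALSE
61,"Asterion_R","R","LM",FALSE
62,"Porion_R","R","LM",FALSE
63,"Zygion_L","L","LM",FALSE
64,"Zygion_R","R","LM",FALSE
65,"Zygomaxillare_L","L","LM",FALSE
66,"Zygomaxillare_R","R","LM",FALSE
67,"Jugale_L","L","LM",FALSE
68,"Jugale_R","R","LM",FALSE
69,"Zygotemporale_L","L","LM",FALSE
70,"Zygotemporale_R","R","LM",FALSE
71,"Malare_L","L","LM",FALSE
72,"Malare_R","R","LM",FALSE
73,"Infratemporale_L","L","LM",FALSE
74,"Infratemporale_R","R","LM",FALSE
75,"Ectomolare_L","L","LM",FALSE
76,"Ectomolare_R","R","LM",FALSE
77,"Endomolare_L","L","LM",FALSE
78,"Endomolare_R","R","LM",FALSE
79,"Mastoidale_L","L","LM",FALSE
80,"Mastoidale_R","R","LM",FALSE
81,"Condylion_laterale_L","L","LM",FALSE
82,"Condylion_laterale_R","R","LM",FALSE
83,"Foramen_magnum_laterale_L","L","LM",FALSE
84,"Foramen_magnum_laterale_R","R","LM",FALSE
85,"Parietale_L","L","LM",FALSE
86,"Parietale_R","R","LM",FALSE
87,"Supraporion_L","L","LM",FALSE
88,"Supraporion_R","R","LM",FALSE
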