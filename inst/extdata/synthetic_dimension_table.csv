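"index","name","endpoint_a","endpoint_b","special"
1,"max_cranial_breadth","Euryon_L","Euryon_R",""
2,"max_cranial_length","Glabella","Opisthocranion",""
3,"cranial_circumference","Glabella","Opisthocranion","circumference"
4,"basion_bregma_height","Basion","Bregma",""
5,"nasion_basion_length","Nasion","Basion",""
6,"glabella_lambda_length","Glabella","Lambda",""
7,"vertex_basion_height","Vertex","Basion",""
8,"biauricular_breadth","Auriculare_L","Auriculare_R",""
9,"biparietal_breadth","Parietale_L","Parietale_R",""
10,"biasterionic_breadth","Asterion_L","Asterion_R",""
11,"frontal_chord","Nasion","Bregma",""
12,"parietal_chord","Bregma","Lambda",""
13,"occipital_chord","Lambda","Opisthion",""
14,"foramen_magnum_length","Basion","Opisthion",""
15,"foramen_magnum_breadth","Foramen_magnum_laterale_L","Foramen_magnum_laterale_R",""
16,"upper_facial_height","Nasion","Prosthion",""
17,"bimastoid_breadth","Mastoidale_L","Mastoidale_R",""
18,"minimum_frontal_breadth","Frontotemporale_L","Frontotemporale_R",""
19,"bizygomatic_breadth","Zygion_L","Zygion_R",""
20,"bistephanic_breadth","Stephanion_L","Stephanion_R",""
21,"bicoronal_breadth","Coronale_L","Coronale_R",""
22,"bipterion_breadth","Pterion_L","Pterion_R",""
23,"bisphenion_breadth","Sphenion_L","Sphenion_R",""
24,"nasal_breadth","Alare_L","Alare_R",""
25,"binariale_breadth","Nariale_L","Nariale_R",""
26,"nasal_height","Nasion","Nasospinale",""
27,"nasion_rhinion_length","Nasion","Rhinion",""
28,"bijugal_breadth","Jugale_L","Jugale_R",""
29,"bimalar_breadth","Malare_L","Malare_R",""
30,"bizygomaxillare_breadth","Zygomaxillare_L","Zygomaxillare_R",""
31,"orbital_breadth_left","Maxillofrontale_L","Ectoconchion_L",""
32,"orbital_breadth_right","Maxillofrontale_R","Ectoconchion_R",""
33,"orbital_height_left","Supraorbitale_L","Orbitale_L",""
34,"orbital_height_right","Supraorbitale_R","Orbitale_R",""
35,"biorbital_breadth","Ectoconchion_L","Ectoconchion_R",""
36,"interorbital_breadth","Maxillofrontale_L","Maxillofrontale_R",""
37,"bidacryonic_breadth","Dacryon_L","Dacryon_R",""
38,"bientomion_breadth","Entomion_L","Entomion_R",""
39,"biporion_breadth","Porion_L","Porion_R",""
40,"bikrotaphion_breadth","Krotaphion_L","Krotaphion_R",""
41,"basion_prosthion_length","Basion","Prosthion",""
42,"glabella_inion_length","Glabella","Inion",""
43,"subspinale_prosthion_height","Subspinale","Prosthion",""
44,"external_palatal_width","Ectomolare_L","Ectomolare_R",""
45,"max_palatal_length","Orale","Staphylion",""
46,"prosthion_staphylion_length","Prosthion","Staphylion",""
47,"internal_palatal_width","Endomolare_L","Endomolare_R",""
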