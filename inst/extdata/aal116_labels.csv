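"index","abbreviation","name","classification"
1,"L.PreCG","Precentral gyrus, left","Frontal"
2,"R.PreCG","Precentral gyrus, right","Frontal"
3,"L.SFGdor","Superior frontal gyrus, dorsolateral, left","Frontal"
4,"R.SFGdor","Superior frontal gyrus, dorsolateral, right","Frontal"
5,"L.ORBsup","Superior frontal gyrus, orbital part, left","Frontal"
6,"R.ORBsup","Superior frontal gyrus, orbital part, right","Frontal"
7,"L.MFG","Middle frontal gyrus, left","Frontal"
8,"R.MFG","Middle frontal gyrus, right","Frontal"
9,"L.ORBmid","Middle frontal gyrus, orbital part, left","Frontal"
10,"R.ORBmid","Middle frontal gyrus, orbital part, right","Frontal"
11,"L.IFGoperc","Inferior frontal gyrus, opercular part, left","Frontal"
12,"R.IFGoperc","Inferior frontal gyrus, opercular part, right","Frontal"
13,"L.IFGtriang","Inferior frontal gyrus, triangular part, left","Frontal"
14,"R.IFGtriang","Inferior frontal gyrus, triangular part, right","Frontal"
15,"L.ORBinf","Inferior frontal gyrus, orbital part, left","Frontal"
16,"R.ORBinf","Inferior frontal gyrus, orbital part, right","Frontal"
17,"L.ROL","Rolandic operculum, left","Frontal"
18,"R.ROL","Rolandic operculum, right","Frontal"
19,"L.SMA","Supplementary motor area, left","Frontal"
20,"R.SMA","Supplementary motor area, right","Frontal"
21,"L.OLF","Olfactory cortex, left","Frontal"
22,"R.OLF","Olfactory cortex, right","Frontal"
23,"L.SFGmed","Superior frontal gyrus, medial, left","Frontal"
24,"R.SFGmed","Superior frontal gyrus, medial, right","Frontal"
25,"L.ORBsupmed","Superior frontal gyrus, medial orbital, left","Frontal"
26,"R.ORBsupmed","Superior frontal gyrus, medial orbital, right","Frontal"
27,"L.REC","Gyrus rectus, left","Frontal"
28,"R.REC","Gyrus rectus, right","Frontal"
29,"L.INS","Insula, left","Insula"
30,"R.INS","Insula, right","Insula"
31,"L.ACG","Anterior cingulate and paracingulate gyri, left","Limbic lobe"
32,"R.ACG","Anterior cingulate and paracingulate gyri, right","Limbic lobe"
33,"L.DCG","Median cingulate and paracingulate gyri, left","Limbic lobe"
34,"R.DCG","Median cingulate and paracingulate gyri, right","Limbic lobe"
35,"L.PCG","Posterior cingulate gyrus, left","Limbic lobe"
36,"R.PCG","Posterior cingulate gyrus, right","Limbic lobe"
37,"L.HIP","Hippocampus, left","Limbic lobe"
38,"R.HIP","Hippocampus, right","Limbic lobe"
39,"L.PHG","Parahippocampal gyrus, left","Limbic lobe"
40,"R.PHG","Parahippocampal gyrus, right","Limbic lobe"
41,"L.AMYG","Amygdala, left","Limbic lobe"
42,"R.AMYG","Amygdala, right","Limbic lobe"
43,"L.CAL","Calcarine fissure and surrounding cortex, left","Occipital"
44,"R.CAL","Calcarine fissure and surrounding cortex, right","Occipital"
45,"L.CUN","Cuneus, left","Occipital"
46,"R.CUN","Cuneus, right","Occipital"
47,"L.LING","Lingual gyrus, left","Occipital"
48,"R.LING","Lingual gyrus, right","Occipital"
49,"L.SOG","Superior occipital gyrus, left","Occipital"
50,"R.SOG","Superior occipital gyrus, right","Occipital"
51,"L.MOG","Middle occipital gyrus, left","Occipital"
52,"R.MOG","Middle occipital gyrus, right","Occipital"
53,"L.IOG","Inferior occipital gyrus, left","Occipital"
54,"R.IOG","Inferior occipital gyrus, right","Occipital"
55,"L.FFG","Fusiform gyrus, left","Temporal"
56,"R.FFG","Fusiform gyrus, right","Temporal"
57,"L.PoCG","Postcentral gyrus, left","Parietal"
58,"R.PoCG","Postcentral gyrus, right","Parietal"
59,"L.SPG","Superior parietal gyrus, left","Parietal"
60,"R.SPG","Superior parietal gyrus, right","Parietal"
61,"L.IPL","Inferior parietal, supramarginal and angular gyri, left","Parietal"
62,"R.IPL","Inferior parietal, supramarginal and angular gyri, right","Parietal"
63,"L.SMG","Supramarginal gyrus, left","Parietal"
64,"R.SMG","Supramarginal gyrus, right","Parietal"
65,"L.ANG","Angular gyrus, left","Parietal"
66,"R.ANG","Angular gyrus, right","Parietal"
67,"L.PCUN","Precuneus, left","Parietal"
68,"R.PCUN","Precuneus, right","Parietal"
69,"L.PCL","Paracentral lobule, left","Frontal"
70,"R.PCL","Paracentral lobule, right","Frontal"
71,"L.CAU","Caudate nucleus, left","Corpus striatum"
72,"R.CAU","Caudate nucleus, right","Corpus striatum"
73,"L.PUT","Lenticular nucleus, putamen, left","Corpus striatum"
74,"R.PUT","Lenticular nucleus, putamen, right","Corpus striatum"
75,"L.PAL","Lenticular nucleus, pallidum, left","Corpus striatum"
76,"R.PAL","Lenticular nucleus, pallidum, right","Corpus striatum"
77,"L.THA","Thalamus, left","Thalamus"
78,"R.THA","Thalamus, right","Thalamus"
79,"L.HES","Heschl gyrus, left","Temporal"
80,"R.HES","Heschl gyrus, right","Temporal"
81,"L.STG","Superior temporal gyrus, left","Temporal"
82,"R.STG","Superior temporal gyrus, right","Temporal"
83,"L.TPOsup","Temporal pole: superior temporal gyrus, left","Limbic lobe"
84,"R.TPOsup","Temporal pole: superior temporal gyrus, right","Limbic lobe"
85,"L.MTG","Middle temporal gyrus, left","Temporal"
86,"R.MTG","Middle temporal gyrus, right","Temporal"
87,"L.TPOmid","Temporal pole: middle temporal gyrus, left","Limbic lobe"
88,"R.TPOmid","Temporal pole: middle temporal gyrus, right","Limbic lobe"
89,"L.ITG","Inferior temporal gyrus, left","Temporal"
90,"R.ITG","Inferior temporal gyrus, right","Temporal"
91,"L.CERCRU1","Cerebellum, crus I, left","Cerebellum"
92,"R.CERCRU1","Cerebellum, crus I, right","Cerebellum"
93,"L.CERCRU2","Cerebellum, crus II, left","Cerebellum"
94,"R.CERCRU2","Cerebellum, crus II, right","Cerebellum"
95,"L.CER3","Cerebellum, lobule III, left","Cerebellum"
96,"R.CER3","Cerebellum, lobule III, right","Cerebellum"
97,"L.CER45","Cerebellum, lobules IV-V, left","Cerebellum"
98,"R.CER45","Cerebellum, lobules IV-V, right","Cerebellum"
99,"L.CER6","Cerebellum, lobule VI, left","Cerebellum"
100,"R.CER6","Cerebellum, lobule VI, right","Cerebellum"
101,"L.CER7","Cerebellum, lobule VIIb, left","Cerebellum"
102,"R.CER7","Cerebellum, lobule VIIb, right","Cerebellum"
103,"L.CER8","Cerebellum, lobule VIII, left","Cerebellum"
104,"R.CER8","Cerebellum, lobule VIII, right","Cerebellum"
105,"L.CER9","Cerebellum, lobule IX, left","Cerebellum"
106,"R.CER9","Cerebellum, lobule IX, right","Cerebellum"
107,"L.CER10","Cerebellum, lobule X, left","Cerebellum"
108,"R.CER10","Cerebellum, lobule X, right","Cerebellum"
109,"VER12","Vermis, lobules I-II","Vermis"
110,"VER3","Vermis, lobule III","Vermis"
111,"VER45","Vermis, lobules IV-V","Vermis"
112,"VER6","Vermis, lobule VI","Vermis"
113,"VER7","Vermis, lobule VII","Vermis"
114,"VER8","Vermis, lobule VIII","Vermis"
115,"VER9","Vermis, lobule IX","Vermis"
116,"VER10","Vermis, lobule X","Vermis"
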