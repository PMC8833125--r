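"id","name","abbreviation","hemisphere"
1,"Nucleus Accumbens Core (right)","AcbC_R","R"
2,"Nucleus Accumbens Shell (right)","AcbSh_R","R"
3,"Amygdala (right)","Amy_R","R"
4,"Bed Nucleus of the Stria Terminalis (right)","BNST_R","R"
5,"Caudate Putamen (right)","CPu_R","R"
6,"Corpus Collosum (right)","CoC_R","R"
7,"Auditory Cortex (right)","Aud_R","R"
8,"Cingulate Cortex (right)","CiC_R","R"
9,"Entorhinal Cortex (right)","EC_R","R"
10,"Frontal Association Cortex (right)","FrA_R","R"
11,"Insular Cortex (right)","In_R","R"
12,"Medial Prefrontal Cortex (right)","mPFC_R","R"
13,"Motor Cortex (right)","M1_R","R"
14,"Orbitofrontal Cortex (right)","OFC_R","R"
15,"Parietal Association Cortex (right)","ParA_R","R"
16,"Piriform Cortex (right)","PC_R","R"
17,"Retrosplenial Cortex (right)","RSC_R","R"
18,"Somatosensory Cortex (right)","S1_R","R"
19,"Temporal Association Cortex (right)","TeA_R","R"
20,"Visual Cortex (right)","V1_R","R"
21,"Diagonal Band (right)","DB_R","R"
22,"Globus Pallidus (right)","GPa_R","R"
23,"Antero-Dorsal Hippocampus (right)","adHIP_R","R"
24,"Posterior Hippocampus (right)","pHIP_R","R"
25,"Postero-Dorsal Hippocampus (right)","pdHIP_R","R"
26,"Hippocampus Subiculum (right)","sHIP_R","R"
27,"Ventral Hippocampus (right)","vHPC_R","R"
28,"Lateral Hypothalamus (right)","LH_R","R"
29,"Medial Hypothalamus (right)","MH_R","R"
30,"Internal Capsule (right)","Ic_R","R"
31,"Interstitial Nucleus of the Posterior Limb of the Anterior Commissure (right)","IPAC_R","R"
32,"Medial Geniculate (right)","MG_R","R"
33,"Mesencephalic Region (right)","MR_R","R"
34,"Olfactory Nuclei (right)","ON_R","R"
35,"Olfactory Tubercle (right)","OT_R","R"
36,"Periaqueductal Grey (right)","PAG_R","R"
37,"Pons (right)","Pons_R","R"
38,"Raphe (right)","Raphe_R","R"
39,"Septum (right)","Septum_R","R"
40,"Substantia Innominata (right)","SI_R","R"
41,"Substantia Nigra (right)","SN_R","R"
42,"Superior Colliculus (right)","SC_R","R"
43,"Dorsolateral Thalamus (right)","DLT_R","R"
44,"Dorsal Midline Thalamus (right)","dMT_R","R"
45,"Ventromedial Thalamus (right)","VMT_R","R"
46,"Ventral Pallidum (right)","VP_R","R"
47,"Ventral Tegmental Area (right)","VTA_R","R"
48,"Zona Incerta (right)","ZI_R","R"
49,"Nucleus Accumbens Core (left)","AcbC_L","L"
50,"Nucleus Accumbens Shell (left)","AcbSh_L","L"
51,"Amygdala (left)","Amy_L","L"
52,"Bed Nucleus of the Stria Terminalis (left)","BNST_L","L"
53,"Caudate Putamen (left)","CPu_L","L"
54,"Corpus Collosum (left)","CoC_L","L"
55,"Auditory Cortex (left)","Aud_L","L"
56,"Cingulate Cortex (left)","CiC_L","L"
57,"Entorhinal Cortex (left)","EC_L","L"
58,"Frontal Association Cortex (left)","FrA_L","L"
59,"Insular Cortex (left)","In_L","L"
60,"Medial Prefrontal Cortex (left)","mPFC_L","L"
61,"Motor Cortex (left)","M1_L","L"
62,"Orbitofrontal Cortex (left)","OFC_L","L"
63,"Parietal Association Cortex (left)","ParA_L","L"
64,"Piriform Cortex (left)","PC_L","L"
65,"Retrosplenial Cortex (left)","RSC_L","L"
66,"Somatosensory Cortex (left)","S1_L","L"
67,"Temporal Association Cortex (left)","TeA_L","L"
68,"Visual Cortex (left)","V1_L","L"
69,"Diagonal Band (left)","DB_L","L"
70,"Globus Pallidus (left)","GPa_L","L"
71,"Antero-Dorsal Hippocampus (left)","adHIP_L","L"
72,"Posterior Hippocampus (left)","pHIP_L","L"
73,"Postero-Dorsal Hippocampus (left)","pdHIP_L","L"
74,"Hippocampus Subiculum (left)","sHIP_L","L"
75,"Ventral Hippocampus (left)","vHPC_L","L"
76,"Lateral Hypothalamus (left)","LH_L","L"
77,"Medial Hypothalamus (left)","MH_L","L"
78,"Internal Capsule (left)","Ic_L","L"
79,"Interstitial Nucleus of the Posterior Limb of the Anterior Commissure (left)","IPAC_L","L"
80,"Medial Geniculate (left)","MG_L","L"
81,"Mesencephalic Region (left)","MR_L","L"
82,"Olfactory Nuclei (left)","ON_L","L"
83,"Olfactory Tubercle (left)","OT_L","L"
84,"Periaqueductal Grey (left)","PAG_L","L"
85,"Pons (left)","Pons_L","L"
86,"Raphe (left)","Raphe_L","L"
87,"Septum (left)","Septum_L","L"
88,"Substantia Innominata (left)","SI_L","L"
89,"Substantia Nigra (left)","SN_L","L"
90,"Superior Colliculus (left)","SC_L","L"
91,"Dorsolateral Thalamus (left)","DLT_L","L"
92,"Dorsal Midline Thalamus (left)","dMT_L","L"
93,"Ventromedial Thalamus (left)","VMT_L","L"
94,"Ventral Pallidum (left)","VP_L","L"
95,"Ventral Tegmental Area (left)","VTA_L","L"
96,"Zona Incerta (left)","ZI_L","L"
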