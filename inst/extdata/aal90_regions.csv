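id,name,hemisphere,homotopic_id
0,Precentral_L,left,45
1,Frontal_Sup_L,left,46
2,Frontal_Sup_Orb_L,left,47
3,Frontal_Mid_L,left,48
4,Frontal_Mid_Orb_L,left,49
5,Frontal_Inf_Oper_L,left,50
6,Frontal_Inf_Tri_L,left,51
7,Frontal_Inf_Orb_L,left,52
8,Rolandic_Oper_L,left,53
9,Supp_Motor_Area_L,left,54
10,Olfactory_L,left,55
11,Frontal_Sup_Medial_L,left,56
12,Frontal_Med_Orb_L,left,57
13,Rectus_L,left,58
14,Insula_L,left,59
15,Cingulum_Ant_L,left,60
16,Cingulum_Mid_L,left,61
17,Cingulum_Post_L,left,62
18,Hippocampus_L,left,63
19,ParaHippocampal_L,left,64
20,Amygdala_L,left,65
21,Calcarine_L,left,66
22,Cuneus_L,left,67
23,Lingual_L,left,68
24,Occipital_Sup_L,left,69
25,Occipital_Mid_L,left,70
26,Occipital_Inf_L,left,71
27,Fusiform_L,left,72
28,Postcentral_L,left,73
29,Parietal_Sup_L,left,74
30,Parietal_Inf_L,left,75
31,SupraMarginal_L,left,76
32,Angular_L,left,77
33,Precuneus_L,left,78
34,Paracentral_Lobule_L,left,79
35,Caudate_L,left,80
36,Putamen_L,left,81
37,Pallidum_L,left,82
38,Thalamus_L,left,83
39,Heschl_L,left,84
40,Temporal_Sup_L,left,85
41,Temporal_Pole_Sup_L,left,86
42,Temporal_Mid_L,left,87
43,Temporal_Pole_Mid_L,left,88
44,Temporal_Inf_L,left,89
45,Precentral_R,right,0
46,Frontal_Sup_R,right,1
47,Frontal_Sup_Orb_R,right,2
48,Frontal_Mid_R,right,3
49,Frontal_Mid_Orb_R,right,4
50,Frontal_Inf_Oper_R,right,5
51,Frontal_Inf_Tri_R,right,6
52,Frontal_Inf_Orb_R,right,7
53,Rolandic_Oper_R,right,8
54,Supp_Motor_Area_R,right,9
55,Olfactory_R,right,10
56,Frontal_Sup_Medial_R,right,11
57,Frontal_Med_Orb_R,right,12
58,Rectus_R,right,13
59,Insula_R,right,14
60,Cingulum_Ant_R,right,15
61,Cingulum_Mid_R,right,16
62,Cingulum_Post_R,right,17
63,Hippocampus_R,right,18
64,ParaHippocampal_R,right,19
65,Amygdala_R,right,20
66,Calcarine_R,right,21
67,Cuneus_R,right,22
68,Lingual_R,right,23
69,Occipital_Sup_R,right,24
70,Occipital_Mid_R,right,25
71,Occipital_Inf_R,right,26
72,Fusiform_R,right,27
73,Postcentral_R,right,28
74,Parietal_Sup_R,right,29
75,Parietal_Inf_R,right,30
76,SupraMarginal_R,right,31
77,Angular_R,right,32
78,Precuneus_R,right,33
79,Paracentral_Lobule_R,right,34
80,Caudate_R,right,35
81,Putamen_R,right,36
82,Pallidum_R,right,37
83,Thalamus_R,right,38
84,Heschl_R,right,39
85,Temporal_Sup_R,right,40
86,Temporal_Pole_Sup_R,right,41
87,Temporal_Mid_R,right,42
88,Temporal_Pole_Mid_R,right,43
89,Temporal_Inf_R,right,44
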