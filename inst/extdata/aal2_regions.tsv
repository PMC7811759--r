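label	long_name	lobe	x	y	z
PreCG	Precentral	central	-39	-6	51
SFG	Frontal_Sup	frontal	-18	35	42
MFG	Frontal_Mid	frontal	-33	33	35
IFGoperc	Frontal_Inf_Oper	frontal	-48	13	19
IFGtriang	Frontal_Inf_Tri	frontal	-46	30	14
IFGorb	Frontal_Inf_Orb	frontal	-46	31	-8
ROL	Rolandic_Oper	central	-47	-8	14
SMA	Supp_Motor_Area	frontal	-5	5	61
OLF	Olfactory	frontal	-8	15	-12
SFGmedial	Frontal_Sup_Medial	frontal	-5	49	31
FMO	Frontal_Med_Orb	frontal	-5	54	-8
REC	Rectus	frontal	-5	37	-18
OFCmed	OFCmed	frontal	-8	47	-14
OFCant	OFCant	frontal	-28	52	-12
OFCpost	OFCpost	frontal	-30	24	-16
OFClat	OFClat	frontal	-40	43	-14
INS	Insula	limbic	-35	7	3
ACC	Cingulate_Ant	limbic	-4	35	14
MCC	Cingulate_Mid	limbic	-5	-15	42
PCC	Cingulate_Post	limbic	-5	-43	25
HIP	Hippocampus	limbic	-25	-21	-10
PHG	ParaHippocampal	limbic	-21	-16	-21
AMYG	Amygdala	limbic	-23	-1	-17
CAL	Calcarine	occipital	-7	-79	6
CUN	Cuneus	occipital	-6	-80	27
LING	Lingual	occipital	-15	-68	-5
SOG	Occipital_Sup	occipital	-17	-84	28
MOG	Occipital_Mid	occipital	-32	-81	16
IOG	Occipital_Inf	occipital	-36	-78	-8
FFG	Fusiform	occipital	-31	-40	-20
PoCG	Postcentral	central	-42	-23	49
SPG	Parietal_Sup	parietal	-23	-60	59
IPG	Parietal_Inf	parietal	-43	-46	47
SMG	SupraMarginal	parietal	-56	-34	30
ANG	Angular	parietal	-44	-61	36
PCUN	Precuneus	parietal	-7	-56	48
PCL	Paracentral_Lobule	central	-8	-25	70
CAU	Caudate	subcortical	-11	11	9
PUT	Putamen	subcortical	-24	4	2
PAL	Pallidum	subcortical	-18	0	0
THA	Thalamus	subcortical	-11	-18	8
HES	Heschl	temporal	-42	-19	10
STG	Temporal_Sup	temporal	-53	-21	7
TPOsup	Temporal_Pole_Sup	temporal	-40	15	-20
MTG	Temporal_Mid	temporal	-56	-34	-2
TPOmid	Temporal_Pole_Mid	temporal	-36	15	-34
ITG	Temporal_Inf	temporal	-50	-28	-23
CB_Crus1	Cerebelum_Crus1	cerebellum	-36	-67	-29
CB_Crus2	Cerebelum_Crus2	cerebellum	-28	-73	-38
CB3	Cerebelum_3	cerebellum	-9	-34	-19
CB4_5	Cerebelum_4_5	cerebellum	-15	-43	-17
CB6	Cerebelum_6	cerebellum	-23	-59	-22
CB7b	Cerebelum_7b	cerebellum	-26	-65	-45
CB8	Cerebelum_8	cerebellum	-25	-56	-48
CB9	Cerebelum_9	cerebellum	-11	-49	-46
CB10	Cerebelum_10	cerebellum	-23	-34	-41
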